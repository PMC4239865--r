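---
title: "Real-time turn detection during gait: model, training and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Real-time turn detection during gait: model, training and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Powered lower-limb prostheses and exoskeletons switch support modes
according to the wearer's intent. A walking turn is one such intent: the
device should know, within a few hundred milliseconds, that a turn has
started, in which direction it goes, and roughly how large it will be.
`turndetect` implements a real-time-capable detector of planned walking
turns from a *single* body-worn inertial measurement unit (IMU), together
with the machinery needed to train and evaluate it: an error-counting
training objective, linear discriminant classifiers for turn direction and
amplitude, two leave-one-out crossvalidation schemes, and a synthetic
gait-trial generator that stands in for human recordings.

Only three vertical-axis (yaw) channels are consumed per IMU: raw
gyroscope angular velocity (deg/s), fused orientation (deg) and
magnetometer heading (arbitrary units). Orientation and heading are
zero-referenced to the standing phase at the start of each trial
(`baseline_subtract()`), so "orientation" always means *change of heading
since trial start*. Sign convention, fixed package-wide: positive angle
and angular velocity denote a left turn (counterclockwise seen from
above).

## The detection rule

A turn is declared at the first sample, scanning from `search_start_ms`
onward, where an enabled criterion is *strictly* exceeded:

* gyroscope criterion: |angular velocity| > `gyr_thresh`;
* orientation criterion: |angle| > `angle_thresh`.

The `combined` criterion enables both and therefore fires at the earlier
of the two crossings; `gyro_only` and `angle_only` disable one check. The
gyroscope tends to fire earlier (the velocity peak precedes most of the
heading change) but is blind to slow turns; the orientation criterion is
never blind to a completed turn but fires late and is exposed to heading
drift. Combining them is the point of the method. A value exactly equal
to a threshold does not fire; when both criteria are exceeded at the same
sample the result records the trigger as `"both"` (the onset time is
unaffected). `detect_onset()` is the batch form; `detect_onset_streaming()`
consumes samples one at a time, uses only past input, and provably equals
the batch form (this equivalence is property-tested on a thousand random
trials).

`search_start_ms` defaults to 1000 ms, the end of the default baseline
window: monitoring begins as soon as the zero reference exists. Subjects
stand for several seconds first, so earlier monitoring would only ever
see standing sway.

## Training the thresholds

Thresholds are trained on a database of labelled trials by minimising an
error count (`detection_cost()`). Per trial:

| situation | penalty |
|---|---|
| turn trial, detected within `tolerance_ms` of the reference onset | 0 |
| turn trial, detected outside the tolerance (premature *or* late) | `premature_late` weight |
| turn trial, not detected | `false_negative` weight |
| straight trial, any detection | `false_positive` weight |
| straight trial, no detection | 0 |

The default tolerance is 500 ms — the sum of a maximum acceptable
actuation delay for an assistive device and the uncertainty of a manually
annotated reference onset — and is deliberately a configuration value,
not a constant. The default weights are all 1; an application that cannot
afford missed turns can raise `false_negative`.

How far a detection lies outside the tolerance does not change its
penalty, so the cost is a piecewise-constant function of the thresholds
with wide flat minima. Two consequences shape the optimiser
(`optimize_thresholds()`):

* For a single enabled threshold the cost is a step function whose jumps
  all lie at values taken by the running maximum of the rectified signal;
  enumerating one representative per plateau is therefore an *exact*
  global minimisation, and that is what the package does for `gyro_only`
  and `angle_only`.
* For the combined criterion the two-dimensional surface is searched with
  a small differential-evolution optimiser (population-based and
  derivative-free — gradients do not exist here), run in log-threshold
  space, initialised from a coarse lattice plus seeded uniform draws, and
  elitist, so the returned cost never increases. It is deterministic
  given `optimizer_seed`.

Because the minima are plateaus, many thresholds tie on the count, and
*where* on the plateau the solution lands matters for generalisation: the
lower edge fires prematurely on excursions the training set happened not
to contain, the upper edge turns borderline-late detections on unseen
trials into misses. Ties are therefore broken to the centre (log scale)
of the widest minimising plateau — the max-margin choice, exact in the
one-dimensional path and approximated by axis-wise centring passes after
the evolutionary search in the combined path. Tests and the acceptance
property always compare *costs*, never threshold identities.

Search bounds default to [1, 300] deg/s and [1, 180] deg. The lower edge
is 1 (not 0) so that log-spacing of the reference grid is well defined;
reported optima for trunk sensors in this literature (tens of deg/s, ~20–30
deg) sit comfortably inside. `grid_search_thresholds()` evaluates a
50-per-dimension log-spaced grid and is the transparent reference the
optimiser is required never to lose to.

`turn_detector()` wraps training into the usual R modelling idiom: it
returns a classed fit with `print()`, `summary()`, `coef()` and
`predict()` methods, where `predict()` runs detection on new trials.

## Direction and amplitude classification

Once onset is declared, a three-value snapshot is read at time
`onset + offset` (offsets 0–500 ms are evaluated): angular velocity,
magnetometer heading and orientation. Direction (left/right) uses the
signed snapshot; amplitude (22/45/90 deg) uses absolute values, since
amplitude is direction-free. Each (location, offset) pair gets its own
linear discriminant model (`train_turn_classifier()`): per-class means, a
pooled within-class covariance (unbiased, n − C denominator), empirical
priors, and the equal-covariance Gaussian decision rule. Exact score ties
go to the first label in `class_labels` order; a numerically singular
pooled covariance receives a ridge of `1e-6 · mean(diag)` (synthetic edge
cases can produce one; realistic data do not).

Training snapshots are taken at the *reference* onset plus offset — the
clean supervised signal — while prediction uses the *detected* onset plus
offset. This mismatch is deliberate and realistic: trials detected late
carry prediction snapshots from a later phase of the turn than the model
was trained on, so accuracy need not rise monotonically with the offset.
On the default cohort, direction is read correctly from the signs
essentially immediately, while amplitude sits at chance (the three
amplitudes have barely diverged at the 5%-crossing onset) and climbs as
the orientation channel separates over the following half second.

## Evaluation protocol

`score_trial()` categorises each (trial, detection) pair: correct
detection (CD, within tolerance), premature/late detection (PLD), missed
turn (FN), false positive (FP, straight trial with a detection), true
negative (TN). `aggregate_outcomes()` turns outcomes into percentages
with the standard denominators — CD, PLD and FN over turn trials (they
sum to exactly 100), FP over straight trials — plus DIFF, the mean
detected-minus-reference difference over detected turn trials (positive =
late).

`crossvalidate()` implements both leave-one-out schemes:

* *subject-independent*: train on all other subjects, test on the
  held-out subject (training folds of 441 trials on the default cohort);
* *within-subject*: per subject, train on all other trials of that
  subject, test on the held-out trial (folds of 48 trials).

Per-trial outcomes are pooled per subject into a subject report, and
subject reports are averaged unweighted — every subject contributes
equally, regardless of trial counts. When a fold holds no straight trial,
FP is reported as missing, never as 0. Classification accuracies are
computed only over correctly detected trials, at the detected onset.
`subset_by_amplitude()` implements the "only larger turns are possible"
experiments: straight trials are always kept, turn trials filtered, and
the filter applies to training and test folds alike.

## The synthetic cohort

No recordings ship with this package; `gait_config()` /
`generate_cohort()` produce the study conditions instead. Defaults encode
the measurement protocol and its timing: 10 subjects, 7 blocks of the 7
travel paths in seeded random order (49 trials each), 100 Hz sampling,
trial duration 16.4 ± 2.2 s, walking from 8.3 ± 2.3 s, reference turn
onset at 10.2 ± 2.3 s. The onset is drawn as walk start plus a gap
(sd `turn_gap_sd` = 0.5 s) because the distance to the turning zone is
fixed; drawing the two independently would force heavy resampling and
bias both means. All draws are resampled until internally consistent
(standing ≥ 2 s, ≥ 1 s of signal beyond onset + 500 ms, turn essentially
complete before the trial ends).

The turn itself is a logistic reorientation
θ(t) = A·L((t − t₀ − lag)/τ): smooth, monotone, with closed-form angular
velocity peaking at A/(4τ) — convenient for parameter-recovery tests. Any
smooth sigmoid would serve; the logistic was chosen for its analytic
derivative. Ground-truth onset is defined as the time the *lag-free*
logistic reaches 5% of its amplitude, a fixed documented proxy for a
human expert's "moment the turn begins". Per-location lags encode the
top-down turning strategy of healthy adults (defaults, ms: head −200,
upper back 0, lower back +30, thighs +100, shanks +150, feet +200);
these magnitudes are literature-motivated placeholders, not measured
values. Healthy peak turn speeds default to 45/75/150 deg/s for 22/45/90°
turns, placing 45° and 90° turns above, and 22° turns below, typical
trained gyroscope thresholds — so small turns are caught later by the
orientation criterion, the mechanism that makes the combined rule win.
Per-subject speed factors (log-normal, sd 0.15) motivate subject-specific
thresholds. The `"amputee"` profile divides peak speeds by 3: slower
turning, smaller velocity peaks, and hence poor transfer of
healthy-trained gyroscope-only thresholds.

Superimposed on the turn are: per-step yaw oscillation (amplitudes 2–8
deg, largest at the feet, at a 0.9-Hz stride rhythm); slow random-walk
drift of the orientation estimate (0.4 deg/√s, applied to the angle and
magnetometer channels only — its implied angular velocity at 100 Hz would
be unrealistic white noise on a gyroscope); white gyroscope noise
(1.5 deg/s); standing sway; brief turn-like transients (head checks, path
corrections: Gaussian heading excursions of 1.5–4 deg over 60–120 ms,
~0.25 per walking second) whose angular-velocity peaks overlap slow small
turns, so a gyroscope threshold alone cannot be error-free; anticipatory
head rotations toward the goal (probability 0.5, ~18 deg), which make the
head location realistically unreliable; and a magnetometer channel that
mirrors the physical heading with extra near-ground disturbance at the
feet. Constant offsets on the angle and magnetometer channels exercise the
baseline-zeroing step.

What the generator does *not* emulate: sagittal-plane gait events,
accelerometer channels, magnetic-field inhomogeneity across the room,
sensor mounting errors, or expert disagreement about reference onsets.
Passing tests on this cohort therefore demonstrate the algorithmic
properties (correct rule, correct training objective, correct evaluation
arithmetic, correct orderings between sensor locations and criteria) —
not field performance on human recordings.

## Numerical choices and degenerate inputs

* Time is milliseconds from the first sample; sample k (0-based) lies at
  k/f_s seconds. Snapshots use the nearest sample; detection uses the
  first sample at or after `search_start_ms`.
* Strict inequalities in the detection rule, as written; the tolerance
  check penalises only differences *greater than* `tolerance_ms`.
* An empty training database has cost 0 by definition (flagged with a
  warning); optimisation on an empty database is an error.
* Baseline windows longer than the series, snapshot times outside the
  series, unknown locations and malformed trial files raise errors naming
  the offending quantity.
* Determinism: every stochastic component (generator, optimiser) is
  seeded; a fixed seed reproduces cohorts and fits bit-identically.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script run on the default 10 × 49
cohort; streaming/batch equivalence uses 1000 generated trials; the
discriminant recovery check compares against a 10⁵-point Monte-Carlo
Bayes-rate oracle; optimiser adequacy is checked against 50-per-dimension
reference grids at six locations × three criteria. Within-subject
crossvalidation (490 folds per configuration) is run at the six evaluated
locations for the ordering properties. These sizes were chosen as the
smallest that exercise every mechanism at the study's own scale.

## Known limitations

* The reference-onset definition (5% crossing) is anchored to the turn's
  own time scale; for very slow turners the early tail of the logistic is
  far ahead of anything measurable, so detections cluster near the
  tolerance boundary — visible in the amputee profile, where even the
  combined criterion loses part of its correct detections. The real
  study's expert annotations plausibly behave similarly, but no
  quantitative comparison is possible without the original recordings.
* Cell values of the original study's result tables derive from
  undeposited human recordings and are out of scope; the package
  reproduces protocol arithmetic and qualitative orderings instead.
* One discriminant model per (location, offset) pair; no sequence
  classifiers, no joint direction-amplitude model, no multi-IMU fusion,
  no online threshold adaptation.
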