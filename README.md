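# turndetect

Real-time detection of walking turns from a single wearable inertial
measurement unit (IMU).

## The problem

Powered lower-limb prostheses and exoskeletons must react to the wearer's
intent within a few hundred milliseconds. A planned walking turn is one
such intent: the device needs to know *that* a turn has started, *which
way* it goes, and roughly *how large* it will be — from body-worn sensors,
causally, with no post-hoc verification pass. `turndetect` implements and
evaluates a method for exactly this, for researchers in wearable-sensor
gait analysis and assistive-device control.

## The method

Three vertical-axis (yaw) channels are used per sensor location: gyroscope
angular velocity ω (deg/s), fused orientation θ (deg) and magnetometer
heading, with θ and the heading zero-referenced to the standing phase at
the start of each trial. Positive values denote a left turn.

**Onset.** A turn is declared at the first sample where an enabled
criterion is strictly exceeded:

    |ω(t)| > gyr_thresh    or    |θ(t)| > angle_thresh

The gyroscope fires early but misses slow turns; the orientation criterion
is never blind but fires late. The `combined` criterion enables both.

**Training.** The two thresholds are trained on labelled trials by
minimising an error count: a detection within 500 ms of the reference
onset is free; premature/late detections, missed turns, and any detection
on a straight-walking trial each add one (configurable weights). The
count is piecewise constant in the thresholds, so it is minimised exactly
(plateau enumeration) for single-threshold criteria and with a seeded
differential-evolution search for the combined criterion; ties on the
count resolve to the centre of the widest minimising plateau.

**Direction and amplitude.** At a configurable offset (0–500 ms) after
the detected onset, the snapshot (ω, magnetometer, θ) feeds a linear
discriminant classifier: signed features for direction (left/right),
absolute features for amplitude (22/45/90°).

**Evaluation.** Within-subject and subject-independent leave-one-out
crossvalidation; metrics CD / PLD / FN (% of turn trials, summing to
100), FP (% of straight trials) and DIFF (mean detected−reference onset,
ms). Because no recordings are distributed, a seeded synthetic gait-trial
generator reproduces the study conditions: 10 subjects × 49 trials in 7
blocks of the 7 travel paths, 100-Hz sampling, walking from 8.3 ± 2.3 s,
turn onset at 10.2 ± 2.3 s, top-down segment reorientation lags (head
first, feet last), per-step yaw oscillation, heading drift, turn-like
transients, anticipatory head rotations, and a slow-turning "amputee"
profile (peak turn speeds ÷ 3).

## Worked example

```r
library(turndetect)

# a synthetic cohort: 10 subjects x 49 trials, all nine sensor locations
cohort <- generate_cohort(gait_config(seed = 1))

# fit the detector at the upper back with both criteria
fit <- turn_detector(cohort, "upper_back", "combined")
fit
#> Turn-onset detector (combined criterion, upper_back IMU)
#>   gyr_thresh:   138.7 deg/s
#>   angle_thresh: 8.9 deg
#>   training cost: 0 error(s) on 490 trials

# detect the onset of one trial
trial <- Filter(function(t) t$path_label == "right_90", cohort)[[1]]
predict(fit, trial)
#> Turn detected at 10500 ms (trigger: angle)
trial$reference_onset_ms
#> [1] 10381.51

# full subject-independent leave-one-out evaluation
report <- crossvalidate(cohort, "subject_independent", "upper_back",
                        training_config(), offsets_ms = c(0, 500))
report
#> Turn-onset evaluation (subject_independent, upper_back, combined)
#>   CD 99.8%  PLD 0.2%  FN 0.0%  FP 0.0%  DIFF 219 ms  (420 turn / 70 straight trials)
#>   direction accuracy (% of CD trials) by offset ms:
#>      0 500
#>    100 100
#>   amplitude accuracy (% of CD trials) by offset ms:
#>       0  500
#>    33.4 83.6
```

Reading the output: at the upper back the angle criterion carries the
detection — the trained angle threshold (8.9°) sits between straight-
walking heading excursions and the smallest turn amplitude, while the
gyroscope threshold centres high in its free band and only fires early
on the fastest turns. On held-out subjects, 99.8% of turns are detected
within 500 ms of the reference onset (on average 219 ms after it), with
no false positives on straight trials. Direction is readable from the
signs essentially immediately; amplitude is at chance (33%) at onset —
the three amplitudes have barely diverged 0 ms into the turn — and
reaches 84% half a second later.

A command-line interface wraps the same functions
(`inst/exec/turndetect`): subcommands `simulate`, `train`, `detect`,
`classify`, `evaluate`, `report`.

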