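#' Configuration of the synthetic gait-trial generator
#'
#' Describes the cohort and signal model used to generate synthetic walking
#' trials that emulate the measurement protocol: each subject performs
#' `blocks` blocks of 7 trials, every block containing all seven travel
#' paths (straight, left/right by 22/45/90 degrees) in seeded random order.
#' The subject stands for several seconds, starts walking on a cue, and
#' turns on reaching the turning zone.
#'
#' The turn itself is a logistic reorientation of each body segment:
#' \eqn{\theta(t) = A \, L((t - t_0 - lag)/\tau)} with signed amplitude `A`
#' (positive = left), midpoint `t_0` and time scale `\tau`, so the angular
#' velocity peaks at `A/(4 tau)`. Per-segment lags encode the top-down
#' turning strategy of healthy adults (head first, feet last). The
#' ground-truth reference onset is the time the lag-free logistic reaches
#' 5% of its amplitude — a fixed, documented proxy for a human expert's
#' "moment when the turn begins". Superimposed on the turn are per-step yaw
#' oscillation, slow heading drift on the orientation estimate, white
#' gyroscope noise, standing sway, anticipatory head rotations, and a
#' magnetometer channel with extra disturbance near the ground (feet).
#'
#' Timing follows the study's statistics: trial duration 16.4 +/- 2.2 s,
#' walking from 8.3 +/- 2.3 s, turn onset at 10.2 +/- 2.3 s (all resampled
#' until internally consistent). The `"amputee"` profile divides the peak
#' turn speeds by 3, mimicking a transfemoral amputee who turns more slowly
#' and therefore shows a much smaller angular-velocity peak: with healthy
#' defaults of 45/75/150 deg/s for 22/45/90-degree turns, the amputee peaks
#' (15/25/50 deg/s) all fall below a gyroscope threshold trained on healthy
#' subjects.
#'
#' @param seed Integer master seed; a fixed seed reproduces the cohort
#'   bit-identically.
#' @param n_subjects,blocks Cohort shape (defaults 10 subjects x 7 blocks =
#'   49 trials each).
#' @param sample_rate Hz (default 100).
#' @param trial_duration_mean,trial_duration_sd,walk_start_mean,walk_start_sd,turn_onset_mean,turn_onset_sd
#'   Timing statistics in seconds.
#' @param profile `"healthy"` or `"amputee"`.
#' @param peak_turn_speed Named vector (`"22"`, `"45"`, `"90"`): peak
#'   angular velocity of each turn amplitude, deg/s, before profile and
#'   subject scaling.
#' @param subject_speed_sd Log-normal sd of the per-subject turn-speed
#'   factor (subjects turn at different speeds, which is what makes
#'   subject-specific thresholds worthwhile).
#' @param segment_lag_ms Named per-location reorientation lags, ms
#'   (negative = earlier than the upper back).
#' @param osc_amp_deg Per-location gait yaw-oscillation amplitude, deg (a
#'   scalar recycles to all locations).
#' @param step_freq_hz Yaw-oscillation (stride) frequency, Hz.
#' @param turn_gap_sd Sd (s) of the walk-to-turn gap: the reference onset
#'   is drawn as walk start plus a gap centred on
#'   `turn_onset_mean - walk_start_mean`, since the distance to the turning
#'   zone is fixed and onset time is therefore correlated with walk start.
#' @param heading_drift_sd Random-walk sd of the orientation estimate,
#'   deg/sqrt(s), active while walking.
#' @param noise_sd White gyroscope noise, deg/s.
#' @param transient_rate Expected number per walking second of brief
#'   turn-like angular-velocity transients (head checks, path corrections):
#'   short Gaussian yaw excursions that return to the original heading.
#'   Their angular-velocity peaks overlap slow small turns, so a gyroscope
#'   threshold alone cannot be error-free — the mechanism that keeps the
#'   orientation criterion useful.
#' @param transient_theta_deg,transient_width_s Ranges (length 2) of the
#'   transient peak heading excursion (deg) and time constant (s).
#' @param sway_amp_deg,sway_freq_hz Standing sway.
#' @param head_anticipation_prob,head_anticipation_deg Probability and
#'   magnitude of an anticipatory head rotation during walking (head
#'   location only; makes head-based detection realistically unreliable).
#' @param mag_gain Heading-to-magnetometer scale (arbitrary units/deg).
#' @param mag_noise_sd,foot_mag_disturb_sd Magnetometer noise; feet get the
#'   extra near-ground disturbance.
#' @param angle_offset_sd,mag_offset_max Constant raw-channel offsets
#'   (removed by [baseline_subtract()]).
#' @param locations Locations to generate (default all nine).
#' @param noise_free Convenience switch zeroing every stochastic signal
#'   component (oscillation, drift, noise, sway, anticipation, magnetometer
#'   noise, subject speed variation) for parameter-recovery checks.
#' @return An object of class `gait_config`.
#' @export
gait_config <- function(seed = 1L,
                        n_subjects = 10L,
                        blocks = 7L,
                        sample_rate = 100,
                        trial_duration_mean = 16.4, trial_duration_sd = 2.2,
                        walk_start_mean = 8.3, walk_start_sd = 2.3,
                        turn_onset_mean = 10.2, turn_onset_sd = 2.3,
                        profile = c("healthy", "amputee"),
                        peak_turn_speed = c("22" = 45, "45" = 75, "90" = 150),
                        subject_speed_sd = 0.15,
                        segment_lag_ms = c(head = -200, upper_back = 0,
                                           lower_back = 30,
                                           left_thigh = 100, right_thigh = 100,
                                           left_shank = 150, right_shank = 150,
                                           left_foot = 200, right_foot = 200),
                        osc_amp_deg = c(head = 2, upper_back = 2,
                                        lower_back = 2.5,
                                        left_thigh = 3, right_thigh = 3,
                                        left_shank = 6, right_shank = 6,
                                        left_foot = 8, right_foot = 8),
                        step_freq_hz = 0.9,
                        turn_gap_sd = 0.5,
                        heading_drift_sd = 0.4,
                        noise_sd = 1.5,
                        transient_rate = 0.25,
                        transient_theta_deg = c(1.5, 4),
                        transient_width_s = c(0.06, 0.12),
                        sway_amp_deg = 0.3, sway_freq_hz = 0.3,
                        head_anticipation_prob = 0.5,
                        head_anticipation_deg = 30,
                        mag_gain = 1,
                        mag_noise_sd = 0.5,
                        foot_mag_disturb_sd = 2,
                        angle_offset_sd = 2,
                        mag_offset_max = 50,
                        locations = sensor_locations(),
                        noise_free = FALSE) {
  profile <- match.arg(profile)
  locations <- match.arg(locations, sensor_locations(), several.ok = TRUE)
  expand <- function(v) {
    if (length(v) == 1L && is.null(names(v)))
      v <- stats::setNames(rep(v, 9), sensor_locations())
    stopifnot(all(sensor_locations() %in% names(v)))
    v
  }
  if (noise_free) {
    osc_amp_deg <- 0; heading_drift_sd <- 0; noise_sd <- 0
    sway_amp_deg <- 0; head_anticipation_prob <- 0
    mag_noise_sd <- 0; foot_mag_disturb_sd <- 0
    angle_offset_sd <- 0; mag_offset_max <- 0
    subject_speed_sd <- 0; transient_rate <- 0
    turn_gap_sd <- 0
  }
  stopifnot(trial_duration_sd >= 0, walk_start_sd >= 0, turn_onset_sd >= 0,
            all(peak_turn_speed > 0), subject_speed_sd >= 0,
            heading_drift_sd >= 0, noise_sd >= 0, sample_rate > 0)
  structure(list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
                 blocks = as.integer(blocks), sample_rate = sample_rate,
                 trial_duration_mean = trial_duration_mean,
                 trial_duration_sd = trial_duration_sd,
                 walk_start_mean = walk_start_mean, walk_start_sd = walk_start_sd,
                 turn_onset_mean = turn_onset_mean, turn_onset_sd = turn_onset_sd,
                 profile = profile,
                 peak_turn_speed = peak_turn_speed,
                 subject_speed_sd = subject_speed_sd,
                 segment_lag_ms = expand(segment_lag_ms),
                 osc_amp_deg = expand(osc_amp_deg),
                 step_freq_hz = step_freq_hz,
                 turn_gap_sd = turn_gap_sd,
                 heading_drift_sd = heading_drift_sd,
                 noise_sd = noise_sd,
                 transient_rate = transient_rate,
                 transient_theta_deg = transient_theta_deg,
                 transient_width_s = transient_width_s,
                 sway_amp_deg = sway_amp_deg, sway_freq_hz = sway_freq_hz,
                 head_anticipation_prob = head_anticipation_prob,
                 head_anticipation_deg = head_anticipation_deg,
                 mag_gain = mag_gain, mag_noise_sd = mag_noise_sd,
                 foot_mag_disturb_sd = foot_mag_disturb_sd,
                 angle_offset_sd = angle_offset_sd,
                 mag_offset_max = mag_offset_max,
                 locations = locations),
            class = "gait_config")
}

# Profile-scaled peak speed for an absolute amplitude (deg/s).
profile_peak_speed <- function(config, abs_amp) {
  p <- config$peak_turn_speed[[as.character(abs_amp)]]
  if (config$profile == "amputee") p / 3 else p
}

# Logistic time scale tau (s) for a turn: peak speed = A / (4 tau).
turn_tau <- function(config, abs_amp, speed_factor = 1) {
  abs_amp / (4 * profile_peak_speed(config, abs_amp) * speed_factor)
}

LOGIT_95 <- log(19)  # lag-free logistic reaches 5% of A at t0 - tau*log(19)

#' Generate one synthetic walking trial
#'
#' Draws trial timing (duration, walk start and — for turn trials — the
#' reference onset, resampled until consistent) and synthesises the three
#' vertical-axis channels for every configured location. Consumes the
#' caller's RNG stream; seed beforehand (or via `seed`) for reproducibility.
#'
#' @param config A [gait_config].
#' @param path_label One of the seven travel paths (see
#'   [trial_recording()]).
#' @param subject_id,trial_id Identifiers.
#' @param speed_factor Per-subject turn-speed factor (drawn by
#'   [generate_session()]).
#' @param seed Optional seed applied locally for a standalone
#'   reproducible trial.
#' @return A [trial_recording].
#' @export
generate_trial <- function(config, path_label, subject_id = "S01",
                           trial_id = "S01_T01", speed_factor = 1,
                           seed = NULL) {
  if (!is.null(seed)) return(with_local_seed(seed, function()
    generate_trial(config, path_label, subject_id, trial_id, speed_factor)))
  path_label <- match.arg(path_label, path_labels())
  fs <- config$sample_rate
  amp <- path_amplitude(path_label)
  is_turn <- amp != 0
  tau <- if (is_turn) turn_tau(config, abs(amp), speed_factor) else NA_real_
  max_lag_s <- max(config$segment_lag_ms[config$locations]) / 1000

  # draw timing, resampled until every constraint holds; the reference
  # onset is walk start plus a gap (fixed distance to the turning zone)
  gap_mean <- config$turn_onset_mean - config$walk_start_mean
  for (try in 1:1000) {
    duration <- stats::rnorm(1, config$trial_duration_mean, config$trial_duration_sd)
    ws <- stats::rnorm(1, config$walk_start_mean, config$walk_start_sd)
    t_ref <- if (is_turn) ws + stats::rnorm(1, gap_mean, config$turn_gap_sd)
             else NA_real_
    ok <- ws >= 2 && duration >= ws + 3
    if (is_turn) {
      t0 <- t_ref + tau * LOGIT_95
      ok <- ok && t_ref >= ws + 0.8 &&
        duration >= t_ref + 1.5 &&                 # >= 1 s beyond onset + max offset
        duration >= t0 + max_lag_s + 3 * tau + 0.3 # turn essentially completes
    }
    if (ok) break
    if (try == 1000) stop("could not draw consistent trial timing; check config")
  }
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  walking <- t >= ws
  env <- stats::plogis((t - ws - 0.5) / 0.2)       # smooth walk onset envelope
  denv <- stats::dlogis((t - ws - 0.5) / 0.2) / 0.2
  phase <- 2 * pi * config$step_freq_hz * (t - ws)
  sway <- config$sway_amp_deg * sin(2 * pi * config$sway_freq_hz * t) *
    (1 - env)
  dsway <- config$sway_amp_deg * 2 * pi * config$sway_freq_hz *
    cos(2 * pi * config$sway_freq_hz * t) * (1 - env) -
    config$sway_amp_deg * sin(2 * pi * config$sway_freq_hz * t) * denv

  # anticipatory head rotation (drawn once; applied to the head channel)
  bump <- NULL
  if (stats::runif(1) < config$head_anticipation_prob) {
    tc_hi <- if (is_turn) min(t_ref - 0.8, duration - 1.5) else duration - 2
    if (tc_hi > ws + 0.5) {
      tc <- stats::runif(1, ws + 0.5, tc_hi)
      m <- config$head_anticipation_deg * stats::runif(1, 0.7, 1.3) *
        (if (is_turn) sign(amp) else sample(c(-1, 1), 1))
      sb <- 0.4
      bump <- list(theta = m * exp(-((t - tc) / sb)^2 / 2),
                   omega = -m * (t - tc) / sb^2 * exp(-((t - tc) / sb)^2 / 2))
    }
  }

  # brief turn-like transients (head checks, path corrections): Gaussian
  # heading excursions that return to zero net rotation
  draw_transients <- function() {
    t_lim <- if (is_turn) t_ref - 0.6 else duration - 0.3
    win <- t_lim - (ws + 0.3)
    if (config$transient_rate <= 0 || win <= 0) return(list(theta = 0, omega = 0))
    k <- stats::rpois(1, config$transient_rate * win)
    th <- om <- numeric(n)
    if (k > 0) for (j in seq_len(k)) {
      tc <- stats::runif(1, ws + 0.3, t_lim)
      w <- stats::runif(1, config$transient_theta_deg[1], config$transient_theta_deg[2]) *
        sample(c(-1, 1), 1)
      sb <- stats::runif(1, config$transient_width_s[1], config$transient_width_s[2])
      g <- exp(-((t - tc) / sb)^2 / 2)
      th <- th + w * g
      om <- om - w * (t - tc) / sb^2 * g
    }
    list(theta = th, omega = om)
  }

  signals <- list()
  for (loc in config$locations) {
    lag <- config$segment_lag_ms[[loc]] / 1000
    if (is_turn) {
      u <- (t - (t0 + lag)) / tau
      th_turn <- amp * stats::plogis(u)
      om_turn <- amp / tau * stats::dlogis(u)
    } else {
      th_turn <- om_turn <- numeric(n)
    }
    a_osc <- config$osc_amp_deg[[loc]]
    th_osc <- a_osc * env * sin(phase)
    om_osc <- a_osc * (denv * sin(phase) +
                         env * 2 * pi * config$step_freq_hz * cos(phase))
    drift <- cumsum(ifelse(walking, stats::rnorm(n, 0, config$heading_drift_sd / sqrt(fs)), 0))
    th_head <- if (identical(loc, "head") && !is.null(bump)) bump$theta else 0
    om_head <- if (identical(loc, "head") && !is.null(bump)) bump$omega else 0
    trans <- draw_transients()

    theta_true <- th_turn + th_osc + sway + th_head + trans$theta  # physical heading
    angle <- theta_true + drift + stats::rnorm(1, 0, config$angle_offset_sd)
    omega <- om_turn + om_osc + dsway + om_head + trans$omega +
      stats::rnorm(n, 0, config$noise_sd)
    mag_sd <- config$mag_noise_sd +
      if (grepl("foot$", loc)) config$foot_mag_disturb_sd else 0
    mag <- config$mag_gain * theta_true +
      stats::rnorm(n, 0, mag_sd) +
      stats::runif(1, -config$mag_offset_max, config$mag_offset_max)
    signals[[loc]] <- va_signals(omega, angle, mag, sample_rate = fs)
  }
  trial_recording(subject_id, trial_id, path_label, signals,
                  reference_onset_ms = if (is_turn) t_ref * 1000 else NULL,
                  walk_start_ms = ws * 1000)
}

#' Generate one subject's session of trials
#'
#' Produces `blocks` blocks of 7 trials; each block is a seeded random
#' permutation of the seven travel paths, so every path occurs exactly
#' `blocks` times. The subject's turn-speed factor is drawn once per
#' subject. Deterministic given `config$seed` and `subject`.
#'
#' @param config A [gait_config].
#' @param subject Subject index (1-based), used to derive the subject seed
#'   and the default `subject_id`.
#' @param subject_id Identifier (default `sprintf("S%02d", subject)`).
#' @return List of `blocks * 7` [trial_recording] objects, with the drawn
#'   `speed_factor` attached as an attribute.
#' @export
#' @examples
#' session <- generate_session(gait_config(blocks = 1, locations = "upper_back"), 1)
#' table(vapply(session, `[[`, "", "path_label"))
generate_session <- function(config, subject,
                             subject_id = sprintf("S%02d", subject)) {
  stopifnot(inherits(config, "gait_config"))
  subject_seed <- (config$seed * 7919L + as.integer(subject) * 104729L) %% 2147483647L
  with_local_seed(subject_seed, function() {
    speed_factor <- exp(stats::rnorm(1, 0, config$subject_speed_sd))
    trials <- vector("list", config$blocks * 7L)
    k <- 0L
    for (b in seq_len(config$blocks)) {
      for (p in sample(path_labels())) {
        k <- k + 1L
        trials[[k]] <- generate_trial(config, p, subject_id,
                                      sprintf("%s_T%02d", subject_id, k),
                                      speed_factor)
      }
    }
    attr(trials, "speed_factor") <- speed_factor
    trials
  })
}

#' Generate a full synthetic cohort
#'
#' Generates `n_subjects` sessions (per-subject turn speeds vary, which is
#' what motivates subject-specific thresholds) and optionally writes them
#' as CSV/JSON trial files plus a manifest.
#'
#' @param config A [gait_config].
#' @param dir Optional output directory; when given, trials and
#'   `manifest.json` are written via [write_cohort()].
#' @return List of all trials (invisibly when `dir` is given).
#' @export
generate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "gait_config"))
  trials <- list()
  for (s in seq_len(config$n_subjects))
    trials <- c(trials, generate_session(config, s))
  if (!is.null(dir)) {
    write_cohort(trials, dir)
    return(invisible(trials))
  }
  trials
}
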