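# Shared fixtures, memoised so expensive cohorts are built once per session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- build()
  .fixture_env[[key]]
}

# The full study-sized cohort: 10 subjects x 49 trials, all nine locations.
default_cohort <- function() {
  memo("default_cohort", function() generate_cohort(gait_config(seed = 1)))
}

# A small cohort for unit tests: 3 subjects x 14 trials, two locations.
small_cohort <- function() {
  memo("small_cohort", function()
    generate_cohort(gait_config(seed = 7, n_subjects = 3, blocks = 2,
                                locations = c("upper_back", "left_foot"))))
}

# Within-subject crossvalidation reports on the default cohort, memoised
# per (location, criterion) so acceptance tests can share them.
ws_report <- function(location, criterion) {
  memo(paste0("ws_", location, "_", criterion), function()
    crossvalidate(default_cohort(), "within_subject", location,
                  training_config(criterion = criterion), offsets_ms = NULL))
}

# Hand-built trial with deterministic signals at one location.
# The angular-velocity and angle series are supplied directly.
make_trial <- function(omega, angle, path_label = "left_90",
                       reference_onset_ms = NULL, location = "upper_back",
                       mag = NULL, subject_id = "SX", trial_id = "SX_T01",
                       walk_start_ms = 0, sample_rate = 100) {
  if (is.null(mag)) mag <- angle
  trial_recording(subject_id, trial_id, path_label,
                  stats::setNames(list(va_signals(omega, angle, mag, sample_rate)),
                                  location),
                  reference_onset_ms = reference_onset_ms,
                  walk_start_ms = walk_start_ms)
}

# Deterministic cost-function building blocks: a turn trial whose
# |angular velocity| jumps from 0 to `peak` at `jump_ms`, and a straight
# trial with a brief excursion of a given peak.
spike_turn_trial <- function(ref_ms, jump_ms, peak = 100, id = "T1",
                             n = 1200) {
  k <- 0:(n - 1)
  omega <- ifelse(k * 10 >= jump_ms, peak, 0)
  make_trial(omega, rep(0, n), "left_45", reference_onset_ms = ref_ms,
             trial_id = id)
}
flat_straight_trial <- function(peak = 0, id = "T2", n = 1200) {
  k <- 0:(n - 1)
  omega <- ifelse(k >= 300 & k < 320, peak, 0)
  make_trial(omega, rep(0, n), "straight", trial_id = id)
}

# Independent linear-scan detection oracle: an explicit sample loop,
# kept deliberately naive and separate from the package implementation.
oracle_detect <- function(omega, angle, gyr, ang_thr, start_ms, fs = 100) {
  for (k in seq_along(omega)) {
    t_ms <- (k - 1) / fs * 1000
    if (t_ms < start_ms) next
    gyro_hit <- !is.na(gyr) && abs(omega[k]) > gyr
    angle_hit <- !is.na(ang_thr) && abs(angle[k]) > ang_thr
    if (gyro_hit || angle_hit)
      return(list(detected = TRUE, onset_ms = t_ms,
                  trigger = if (gyro_hit && angle_hit) "both"
                            else if (gyro_hit) "gyro" else "angle"))
  }
  list(detected = FALSE, onset_ms = NULL, trigger = NULL)
}

# Independent brute-force cost oracle: enumerates the four penalty
# branches per trial using oracle_detect.
oracle_cost <- function(thresholds, database, location, tolerance_ms = 500,
                        weights = c(1, 1, 1), start_ms = 1000,
                        baseline_window_s = 1) {
  total <- 0
  for (trial in database) {
    sig <- baseline_subtract(trial$signals[[location]], baseline_window_s)
    res <- oracle_detect(sig$angular_velocity, sig$angle,
                         thresholds$gyr_thresh, thresholds$angle_thresh,
                         start_ms, sig$sample_rate)
    if (trial$path_label == "straight") {
      if (res$detected) total <- total + weights[3]
    } else if (!res$detected) {
      total <- total + weights[2]
    } else if (abs(res$onset_ms - trial$reference_onset_ms) > tolerance_ms) {
      total <- total + weights[1]
    }
  }
  total
}
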