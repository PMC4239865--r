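#' Sensor locations
#'
#' The nine body locations at which an inertial measurement unit (IMU) may be
#' worn: head, upper back, lower back, and thigh/shank/foot on each side.
#' Signals from any one location are sufficient for turn detection; trunk
#' locations detect on-the-move turns earliest because healthy adults turn
#' "top-down" (head first, feet last).
#'
#' @return Character vector of the nine location labels.
#' @export
#' @examples
#' sensor_locations()
sensor_locations <- function() {
  c("head", "upper_back", "lower_back",
    "left_thigh", "right_thigh",
    "left_shank", "right_shank",
    "left_foot", "right_foot")
}

#' Vertical-axis IMU signals for one trial
#'
#' Bundles the three vertical-axis (yaw) channels consumed by the turn
#' detector: raw gyroscope angular velocity (deg/s), fused orientation
#' (deg) and magnetometer heading (arbitrary units), all sampled at a
#' common rate. Sign convention: positive angle and angular velocity denote
#' a left turn (counterclockwise viewed from above).
#'
#' @param angular_velocity Numeric vector, deg/s about the vertical axis.
#' @param angle Numeric vector, deg about the vertical axis.
#' @param mag_heading Numeric vector, magnetometer heading (arbitrary units).
#' @param sample_rate Sampling rate in Hz (default 100).
#' @return An object of class `va_signals`.
#' @export
#' @examples
#' s <- va_signals(rnorm(100), rnorm(100), rnorm(100))
#' length(s$angle)
va_signals <- function(angular_velocity, angle, mag_heading, sample_rate = 100) {
  angular_velocity <- as.numeric(angular_velocity)
  angle <- as.numeric(angle)
  mag_heading <- as.numeric(mag_heading)
  n <- length(angular_velocity)
  if (n < 1L) stop("signals must contain at least one sample")
  if (length(angle) != n || length(mag_heading) != n)
    stop("angular_velocity, angle and mag_heading must have equal length")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("sample_rate must be a positive scalar")
  structure(
    list(angular_velocity = angular_velocity, angle = angle,
         mag_heading = mag_heading, sample_rate = as.numeric(sample_rate)),
    class = "va_signals")
}

#' @export
print.va_signals <- function(x, ...) {
  cat(sprintf("Vertical-axis IMU signals: %d samples @ %g Hz (%.2f s)\n",
              length(x$angle), x$sample_rate, length(x$angle) / x$sample_rate))
  invisible(x)
}

#' @export
length.va_signals <- function(x) length(x$angle)

# Sample times in ms from trial start; sample k (0-based) lies at k/fs seconds.
signal_times_ms <- function(signals) {
  (seq_along(signals$angle) - 1) / signals$sample_rate * 1000
}

# Nearest-sample index (1-based) for a time in ms; errors outside the series.
sample_index_at <- function(signals, t_ms, what = "time") {
  n <- length(signals$angle)
  idx <- round(t_ms / 1000 * signals$sample_rate) + 1L
  if (is.na(idx) || idx < 1L || idx > n)
    stop(sprintf("%s %.1f ms is outside the recorded series (0..%.1f ms)",
                 what, t_ms, (n - 1) / signals$sample_rate * 1000))
  as.integer(idx)
}

#' Zero-reference orientation and heading to the start of a trial
#'
#' Subtracts the mean of the orientation and magnetometer channels over an
#' initial baseline window (while the subject is still standing) from the
#' whole series, so both start near zero. The gyroscope channel is returned
#' unchanged. The operation is idempotent: applying it twice is the same as
#' applying it once.
#'
#' @param signals A [va_signals] object.
#' @param baseline_window_s Length of the baseline window in seconds
#'   (default 1). Must be positive and no longer than the series.
#' @return A [va_signals] object with zero-referenced `angle` and
#'   `mag_heading`.
#' @export
#' @examples
#' s <- va_signals(rep(0, 200), rep(17, 200), rep(-4, 200))
#' z <- baseline_subtract(s)
#' range(z$angle)
baseline_subtract <- function(signals, baseline_window_s = 1) {
  stopifnot(inherits(signals, "va_signals"))
  if (!is.numeric(baseline_window_s) || baseline_window_s <= 0)
    stop("baseline_window_s must be positive")
  n <- length(signals$angle)
  k <- floor(baseline_window_s * signals$sample_rate)
  if (k < 1L) k <- 1L
  if (k > n)
    stop(sprintf("baseline window (%.2f s) is longer than the series (%.2f s)",
                 baseline_window_s, n / signals$sample_rate))
  signals$angle <- signals$angle - mean(signals$angle[seq_len(k)])
  signals$mag_heading <- signals$mag_heading - mean(signals$mag_heading[seq_len(k)])
  signals
}

#' A single labelled walking trial
#'
#' One trial of the measurement protocol: the subject stands, starts walking
#' on a verbal cue, and on reaching the turning zone either continues
#' straight or turns left/right by 22, 45 or 90 degrees. Holds the
#' vertical-axis signal triple for each instrumented location plus the
#' ground-truth labels.
#'
#' @param subject_id,trial_id Identifiers.
#' @param path_label One of `"straight"`, `"left_22"`, `"left_45"`,
#'   `"left_90"`, `"right_22"`, `"right_45"`, `"right_90"`.
#' @param signals Named list mapping location labels (see
#'   [sensor_locations()]) to [va_signals] objects, all of equal length and
#'   sample rate.
#' @param reference_onset_ms Reference turn onset in ms from trial start;
#'   must be `NULL` exactly when `path_label == "straight"`.
#' @param walk_start_ms Time in ms at which the subject starts walking.
#' @return An object of class `trial_recording`.
#' @export
trial_recording <- function(subject_id, trial_id, path_label, signals,
                            reference_onset_ms = NULL, walk_start_ms = 0) {
  path_label <- match.arg(path_label, path_labels())
  if (!is.list(signals) || length(signals) < 1L || is.null(names(signals)))
    stop("signals must be a non-empty named list of va_signals")
  bad <- setdiff(names(signals), sensor_locations())
  if (length(bad))
    stop("unknown sensor location(s): ", paste(bad, collapse = ", "))
  lens <- vapply(signals, function(s) length(s$angle), integer(1))
  rates <- vapply(signals, function(s) s$sample_rate, numeric(1))
  if (length(unique(lens)) != 1L || length(unique(rates)) != 1L)
    stop("all locations in one trial must share series length and sample rate")
  dur_ms <- (lens[[1]] - 1) / rates[[1]] * 1000
  if (path_label == "straight") {
    if (!is.null(reference_onset_ms))
      stop("reference_onset_ms must be absent for a straight trial")
  } else {
    if (is.null(reference_onset_ms))
      stop("reference_onset_ms is required for a turn trial")
    if (walk_start_ms > reference_onset_ms || reference_onset_ms >= dur_ms + 1000 / rates[[1]])
      stop("require walk_start_ms <= reference_onset_ms < trial duration")
  }
  structure(
    list(subject_id = as.character(subject_id),
         trial_id = as.character(trial_id),
         path_label = path_label,
         signals = signals,
         reference_onset_ms = if (is.null(reference_onset_ms)) NULL else as.numeric(reference_onset_ms),
         walk_start_ms = as.numeric(walk_start_ms)),
    class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  s <- x$signals[[1]]
  cat(sprintf("Trial %s / %s: path %s, %d locations, %.1f s @ %g Hz\n",
              x$subject_id, x$trial_id, x$path_label, length(x$signals),
              length(s$angle) / s$sample_rate, s$sample_rate))
  if (!is.null(x$reference_onset_ms))
    cat(sprintf("  reference onset %.0f ms, walking from %.0f ms\n",
                x$reference_onset_ms, x$walk_start_ms))
  invisible(x)
}

path_labels <- function() {
  c("straight", "left_22", "left_45", "left_90",
    "right_22", "right_45", "right_90")
}

# Signed turn amplitude in degrees for a path label (0 for straight,
# positive = left by the package sign convention).
path_amplitude <- function(path_label) {
  amp <- c(straight = 0, left_22 = 22, left_45 = 45, left_90 = 90,
           right_22 = -22, right_45 = -45, right_90 = -90)
  unname(amp[path_label])
}
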