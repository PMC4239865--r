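#' Detection thresholds
#'
#' The pair of thresholds used by the turn-onset rule: a turn is declared at
#' the first sample where the absolute vertical-axis angular velocity
#' strictly exceeds `gyr_thresh`, or the absolute zero-referenced
#' orientation strictly exceeds `angle_thresh`. The `criterion` selects
#' which checks are enabled; a disabled threshold is stored as `NA`.
#'
#' @param gyr_thresh Angular-velocity threshold, deg/s (`NA` when the
#'   criterion is `angle_only`).
#' @param angle_thresh Orientation threshold, deg (`NA` when the criterion
#'   is `gyro_only`).
#' @param criterion One of `"combined"`, `"gyro_only"`, `"angle_only"`.
#' @return An object of class `threshold_pair`.
#' @export
#' @examples
#' threshold_pair(58, 23)  # subject-independent optima reported for the upper back
threshold_pair <- function(gyr_thresh = NA, angle_thresh = NA,
                           criterion = c("combined", "gyro_only", "angle_only")) {
  criterion <- match.arg(criterion)
  gyr_on <- criterion %in% c("combined", "gyro_only")
  ang_on <- criterion %in% c("combined", "angle_only")
  if (gyr_on && (is.na(gyr_thresh) || gyr_thresh <= 0))
    stop("gyr_thresh must be > 0 for criterion ", criterion)
  if (ang_on && (is.na(angle_thresh) || angle_thresh <= 0))
    stop("angle_thresh must be > 0 for criterion ", criterion)
  structure(list(gyr_thresh = if (gyr_on) as.numeric(gyr_thresh) else NA_real_,
                 angle_thresh = if (ang_on) as.numeric(angle_thresh) else NA_real_,
                 criterion = criterion),
            class = "threshold_pair")
}

#' @export
print.threshold_pair <- function(x, ...) {
  cat(sprintf("Turn-detection thresholds (%s): gyr %s deg/s, angle %s deg\n",
              x$criterion,
              if (is.na(x$gyr_thresh)) "-" else format(x$gyr_thresh),
              if (is.na(x$angle_thresh)) "-" else format(x$angle_thresh)))
  invisible(x)
}

detection_result <- function(detected, onset_ms = NULL, trigger = NULL) {
  structure(list(detected = detected,
                 onset_ms = if (detected) onset_ms else NULL,
                 trigger = if (detected) trigger else NULL),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  if (x$detected)
    cat(sprintf("Turn detected at %.0f ms (trigger: %s)\n", x$onset_ms, x$trigger))
  else cat("No turn detected\n")
  invisible(x)
}

#' Detect turn onset in a completed trial (batch)
#'
#' Scans the series from `search_start_ms` onward and declares onset at the
#' earliest sample where an enabled criterion is strictly exceeded:
#' `|angular velocity| > gyr_thresh` or `|angle| > angle_thresh`. A value
#' exactly equal to a threshold does not fire. `trigger` records which
#' criterion fired (the gyroscope check comes first; `"both"` when both
#' exceed at the same sample).
#'
#' Signals are expected zero-referenced (see [baseline_subtract()]): the
#' angle criterion compares orientation relative to the trial start, so
#' heading drift during straight walking is a genuine false-positive
#' mechanism.
#'
#' @param signals A baseline-zeroed [va_signals] object.
#' @param thresholds A [threshold_pair].
#' @param search_start_ms Monitoring start time, ms from trial start
#'   (default 1000, the end of the default baseline window).
#' @return A `detection_result`: `detected` (logical), and when detected
#'   `onset_ms` (coincides with a sample time) and `trigger` (`"gyro"`,
#'   `"angle"` or `"both"`).
#' @seealso [detect_onset_streaming()] for the sample-by-sample form.
#' @export
#' @examples
#' w <- c(rep(0, 500), seq(0, 120, length.out = 300))
#' s <- va_signals(w, rep(0, 800), rep(0, 800))
#' detect_onset(s, threshold_pair(58, criterion = "gyro_only"))
detect_onset <- function(signals, thresholds, search_start_ms = 1000) {
  stopifnot(inherits(signals, "va_signals"), inherits(thresholds, "threshold_pair"))
  n <- length(signals$angle)
  # first sample at or after search_start_ms (matching the streaming form)
  i0 <- as.integer(ceiling(search_start_ms / 1000 * signals$sample_rate - 1e-9)) + 1L
  if (search_start_ms < 0 || i0 > n)
    stop(sprintf("search_start_ms %.1f ms is outside the recorded series (0..%.1f ms)",
                 search_start_ms, (n - 1) / signals$sample_rate * 1000))
  idx <- i0:n
  gyro_hit <- if (is.na(thresholds$gyr_thresh)) rep(FALSE, length(idx))
              else abs(signals$angular_velocity[idx]) > thresholds$gyr_thresh
  angle_hit <- if (is.na(thresholds$angle_thresh)) rep(FALSE, length(idx))
               else abs(signals$angle[idx]) > thresholds$angle_thresh
  hit <- which(gyro_hit | angle_hit)
  if (!length(hit)) return(detection_result(FALSE))
  k <- hit[1L]
  trigger <- if (gyro_hit[k] && angle_hit[k]) "both" else if (gyro_hit[k]) "gyro" else "angle"
  onset_ms <- (idx[k] - 1) / signals$sample_rate * 1000
  detection_result(TRUE, onset_ms, trigger)
}

#' Detect turn onset from a streamed feed (real-time form)
#'
#' Consumes `(angular velocity, angle)` samples one at a time, deciding from
#' each sample using only past input, as an assistive device would at run
#' time. Equivalent to [detect_onset()] on the completed series; once fired
#' it ignores further input.
#'
#' @param feed A function returning the next sample as
#'   `c(angular_velocity, angle)`, or `NULL` when the feed ends; or a
#'   [va_signals] object (replayed sample by sample).
#' @param thresholds A [threshold_pair].
#' @param sample_rate Sampling rate in Hz (taken from `feed` when it is a
#'   [va_signals]).
#' @param search_start_ms Monitoring start time, ms (default 1000).
#' @return A `detection_result`, as for [detect_onset()].
#' @export
detect_onset_streaming <- function(feed, thresholds, sample_rate = 100,
                                   search_start_ms = 1000) {
  stopifnot(inherits(thresholds, "threshold_pair"))
  if (inherits(feed, "va_signals")) {
    sig <- feed
    sample_rate <- sig$sample_rate
    i <- 0L
    n <- length(sig$angle)
    feed <- function() {
      if (i >= n) return(NULL)
      i <<- i + 1L
      c(sig$angular_velocity[i], sig$angle[i])
    }
  }
  g <- thresholds$gyr_thresh
  a <- thresholds$angle_thresh
  k <- 0L  # 0-based sample counter
  repeat {
    smp <- feed()
    if (is.null(smp)) return(detection_result(FALSE))
    t_ms <- k / sample_rate * 1000
    if (t_ms >= search_start_ms) {
      gyro_hit <- !is.na(g) && abs(smp[1L]) > g
      angle_hit <- !is.na(a) && abs(smp[2L]) > a
      if (gyro_hit || angle_hit) {
        trigger <- if (gyro_hit && angle_hit) "both" else if (gyro_hit) "gyro" else "angle"
        return(detection_result(TRUE, t_ms, trigger))
      }
    }
    k <- k + 1L
  }
}
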