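#' Fit a turn-onset detector to a database of labelled trials
#'
#' The central fitting function of the package. Given a training database of
#' walking trials with known reference turn onsets (and straight trials
#' without a turn), it trains the two detection thresholds — on absolute
#' vertical-axis angular velocity and on absolute zero-referenced
#' orientation — by minimising the error-counting cost of
#' [detection_cost()]: every premature/late detection, missed turn and
#' straight-trial detection counts against a candidate threshold pair.
#'
#' @param database List of [trial_recording] objects.
#' @param location Sensor location whose signals the detector uses (see
#'   [sensor_locations()]; the trunk locations work best for on-the-move
#'   turns).
#' @param criterion `"combined"` (both thresholds), `"gyro_only"` or
#'   `"angle_only"`.
#' @param config A [training_config]; its `criterion` is overridden by the
#'   `criterion` argument.
#' @return An object of class `turn_detector` with components `thresholds`
#'   (a [threshold_pair]), `cost`, `location`, `config`, `n_trials`.
#' @seealso [predict.turn_detector()], [crossvalidate()].
#' @export
#' @examples
#' cohort <- generate_session(gait_config(n_subjects = 1, blocks = 2,
#'                                        locations = "upper_back"), 1)
#' fit <- turn_detector(cohort, "upper_back")
#' fit
#' coef(fit)
#' predict(fit, cohort[[1]])
turn_detector <- function(database, location,
                          criterion = c("combined", "gyro_only", "angle_only"),
                          config = training_config()) {
  criterion <- match.arg(criterion)
  config$criterion <- criterion
  location <- match.arg(location, sensor_locations())
  fit <- optimize_thresholds(database, location, config)
  structure(list(thresholds = fit$thresholds, cost = fit$cost,
                 location = location, config = config,
                 n_trials = length(database)),
            class = "turn_detector")
}

#' @export
print.turn_detector <- function(x, ...) {
  cat(sprintf("Turn-onset detector (%s criterion, %s IMU)\n",
              x$thresholds$criterion, x$location))
  cat(sprintf("  gyr_thresh:   %s deg/s\n",
              if (is.na(x$thresholds$gyr_thresh)) "disabled"
              else sprintf("%.1f", x$thresholds$gyr_thresh)))
  cat(sprintf("  angle_thresh: %s deg\n",
              if (is.na(x$thresholds$angle_thresh)) "disabled"
              else sprintf("%.1f", x$thresholds$angle_thresh)))
  cat(sprintf("  training cost: %g error(s) on %d trials\n", x$cost, x$n_trials))
  invisible(x)
}

#' @export
summary.turn_detector <- function(object, ...) {
  print(object)
  cat(sprintf("  tolerance: %g ms; search from %g ms; weights PLD/FN/FP = %s\n",
              object$config$tolerance_ms, object$config$search_start_ms,
              paste(object$config$error_weights, collapse = "/")))
  invisible(object)
}

#' @export
coef.turn_detector <- function(object, ...) {
  c(gyr_thresh = object$thresholds$gyr_thresh,
    angle_thresh = object$thresholds$angle_thresh)
}

#' Detect turn onset in new trials with a fitted detector
#'
#' Applies the trained thresholds to one trial (or a list of trials),
#' zero-referencing the signals first.
#'
#' @param object A fitted [turn_detector].
#' @param newdata A [trial_recording], a list of them, or a [va_signals]
#'   object (assumed already zero-referenced).
#' @param ... Unused.
#' @return A `detection_result`, or a list of them for a list input.
#' @export
predict.turn_detector <- function(object, newdata, ...) {
  one <- function(trial) {
    sig <- if (inherits(trial, "va_signals")) trial
           else zeroed_signals(trial, object$location, object$config)
    detect_onset(sig, object$thresholds, object$config$search_start_ms)
  }
  if (inherits(newdata, c("trial_recording", "va_signals"))) one(newdata)
  else lapply(newdata, one)
}
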