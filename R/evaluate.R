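#' Score one detection result against a trial's ground truth
#'
#' Categorises the outcome of running the detector on one trial:
#' * turn trial, detected within the tolerance of the reference onset
#'   — correct detection (`CD`);
#' * turn trial, detected outside the tolerance — premature or late
#'   detection (`PLD`);
#' * turn trial, not detected — false negative (`FN`);
#' * straight trial, detected — false positive (`FP`);
#' * straight trial, not detected — true negative (`TN`).
#'
#' @param trial A [trial_recording].
#' @param result A `detection_result` produced on this trial.
#' @param tolerance_ms Detection tolerance in ms (default 500).
#' @return An object of class `trial_outcome` with `category` and, for
#'   CD/PLD, `diff_ms` = detected minus reference onset (positive = late).
#' @export
score_trial <- function(trial, result, tolerance_ms = 500) {
  stopifnot(inherits(trial, "trial_recording"), inherits(result, "detection_result"))
  if (trial$path_label == "straight") {
    category <- if (result$detected) "FP" else "TN"
    diff_ms <- NULL
  } else if (!result$detected) {
    category <- "FN"
    diff_ms <- NULL
  } else {
    diff_ms <- result$onset_ms - trial$reference_onset_ms
    category <- if (abs(diff_ms) <= tolerance_ms) "CD" else "PLD"
  }
  structure(list(category = category, diff_ms = diff_ms), class = "trial_outcome")
}

#' Aggregate trial outcomes into the five onset-detection metrics
#'
#' Computes, with the standard denominators:
#' * `cd_pct`, `pld_pct`, `fn_pct` — percentages of turn trials (they sum
#'   to 100 exactly);
#' * `fp_pct` — percentage of straight (no-turn) trials with a detection
#'   (`NA` when the set contains no straight trial);
#' * `diff_ms_mean` — mean detected-minus-reference onset difference over
#'   CD and PLD trials, positive = detected late.
#'
#' @param outcomes Non-empty list of `trial_outcome` objects.
#' @return An object of class `evaluation_report`.
#' @export
aggregate_outcomes <- function(outcomes) {
  if (!length(outcomes)) stop("cannot aggregate an empty outcome list")
  cats <- vapply(outcomes, `[[`, "", "category")
  n_turn <- sum(cats %in% c("CD", "PLD", "FN"))
  n_straight <- sum(cats %in% c("FP", "TN"))
  diffs <- unlist(lapply(outcomes, `[[`, "diff_ms"))
  rep <- list(
    cd_pct = if (n_turn) 100 * sum(cats == "CD") / n_turn else NA_real_,
    pld_pct = if (n_turn) 100 * sum(cats == "PLD") / n_turn else NA_real_,
    fn_pct = if (n_turn) 100 * sum(cats == "FN") / n_turn else NA_real_,
    fp_pct = if (n_straight) 100 * sum(cats == "FP") / n_straight else NA_real_,
    diff_ms_mean = if (length(diffs)) mean(diffs) else NA_real_,
    n_turn_trials = n_turn,
    n_straight_trials = n_straight)
  structure(rep, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  fmt <- function(v, d = 1) if (is.null(v) || is.na(v)) "-" else sprintf(paste0("%.", d, "f"), v)
  cat("Turn-onset evaluation", if (!is.null(x$scheme)) sprintf("(%s, %s, %s)", x$scheme, x$location, x$criterion), "\n")
  cat(sprintf("  CD %s%%  PLD %s%%  FN %s%%  FP %s%%  DIFF %s ms  (%d turn / %d straight trials)\n",
              fmt(x$cd_pct), fmt(x$pld_pct), fmt(x$fn_pct), fmt(x$fp_pct),
              fmt(x$diff_ms_mean, 0), x$n_turn_trials, x$n_straight_trials))
  if (!is.null(x$direction_accuracy_pct) && length(x$direction_accuracy_pct)) {
    cat("  direction accuracy (% of CD trials) by offset ms:\n   ")
    print(round(x$direction_accuracy_pct, 1))
    cat("  amplitude accuracy (% of CD trials) by offset ms:\n   ")
    print(round(x$amplitude_accuracy_pct, 1))
  }
  invisible(x)
}

#' Restrict a cohort to selected turn amplitudes
#'
#' Keeps every straight trial and the turn trials whose absolute amplitude
#' is in `keep`. Used for the "only larger turns are possible" analyses:
#' dropping 22-degree (and 45-degree) turns from both training and test
#' sets shows how much detection improves when small turns need not be
#' caught.
#'
#' @param cohort List of [trial_recording] objects.
#' @param keep Subset of `c(22, 45, 90)` (non-empty).
#' @return Filtered list of trials.
#' @export
subset_by_amplitude <- function(cohort, keep) {
  if (!length(keep) || !all(keep %in% c(22, 45, 90)))
    stop("keep must be a non-empty subset of {22, 45, 90}")
  Filter(function(tr) {
    a <- abs(path_amplitude(tr$path_label))
    a == 0 || a %in% keep
  }, cohort)
}

# Per-offset classification over correctly detected turn trials.
# Returns percentage vectors named by offset; NA where no CD trial exists.
classify_fold <- function(train, test_outcomes, location, offsets_ms, config) {
  n_off <- length(offsets_ms)
  dir_models <- lapply(offsets_ms, function(o)
    train_turn_classifier(train, location, o, "direction", config))
  amp_models <- lapply(offsets_ms, function(o)
    train_turn_classifier(train, location, o, "amplitude", config))
  dir_ok <- dir_n <- amp_ok <- numeric(n_off)
  for (rec in test_outcomes) {
    if (rec$outcome$category != "CD") next
    trial <- rec$trial
    onset <- rec$result$onset_ms
    true_dir <- if (path_amplitude(trial$path_label) > 0) "left" else "right"
    true_amp <- abs(path_amplitude(trial$path_label))
    for (k in seq_len(n_off)) {
      pd <- classify_direction(dir_models[[k]], trial, location, onset,
                               offsets_ms[k], config)
      pa <- classify_amplitude(amp_models[[k]], trial, location, onset,
                               offsets_ms[k], config)
      dir_ok[k] <- dir_ok[k] + (pd == true_dir)
      amp_ok[k] <- amp_ok[k] + (pa == true_amp)
      dir_n[k] <- dir_n[k] + 1
    }
  }
  list(direction = stats::setNames(ifelse(dir_n > 0, 100 * dir_ok / dir_n, NA_real_), offsets_ms),
       amplitude = stats::setNames(ifelse(dir_n > 0, 100 * amp_ok / dir_n, NA_real_), offsets_ms))
}

#' Leave-one-out crossvalidation of the full turn-detection pipeline
#'
#' Evaluates threshold training, onset detection and (optionally)
#' direction/amplitude classification under one of two schemes:
#' * `subject_independent` — leave one subject out: thresholds and
#'   classifiers are trained on all other subjects' trials and evaluated on
#'   the held-out subject; one report per subject.
#' * `within_subject` — per subject, leave one trial out: train on the
#'   subject's remaining trials, evaluate on the held-out trial; the
#'   subject's per-trial outcomes are pooled into one report per subject.
#'
#' Subject reports are averaged unweighted (every subject contributes
#' equally). Classification accuracies are computed only over trials whose
#' onset was detected correctly, using the detected onset.
#'
#' @param cohort List of [trial_recording] objects covering >= 2 subjects
#'   (subject-independent) or >= 2 trials per subject (within-subject).
#' @param scheme `"subject_independent"` or `"within_subject"`.
#' @param location Sensor location.
#' @param config A [training_config] (criterion, tolerance, optimiser
#'   settings).
#' @param offsets_ms Snapshot offsets for classification, ms; `NULL` skips
#'   classification (onset metrics only).
#' @param detector Optional detector override for diagnostics: a function
#'   `function(trial)` returning a `detection_result`; when supplied, no
#'   threshold training is performed.
#' @return An `evaluation_report` (averaged across subjects) with
#'   additional components `per_subject` (list of per-subject reports),
#'   `fold_train_sizes`, `scheme`, `location`, `criterion`.
#' @export
crossvalidate <- function(cohort,
                          scheme = c("subject_independent", "within_subject"),
                          location = "upper_back",
                          config = training_config(),
                          offsets_ms = c(0, 100, 200, 300, 400, 500),
                          detector = NULL) {
  scheme <- match.arg(scheme)
  location <- match.arg(location, sensor_locations())
  subjects <- unique(vapply(cohort, `[[`, "", "subject_id"))
  by_subject <- lapply(subjects, function(s)
    Filter(function(tr) tr$subject_id == s, cohort))
  names(by_subject) <- subjects
  if (scheme == "subject_independent" && length(subjects) < 2L)
    stop("subject_independent crossvalidation needs >= 2 subjects")
  if (scheme == "within_subject" &&
      any(vapply(by_subject, length, 0L) < 2L))
    stop("within_subject crossvalidation needs >= 2 trials per subject")

  eval_trial <- function(fit, trial) {
    result <- if (!is.null(detector)) detector(trial) else predict(fit, trial)
    list(trial = trial, result = result,
         outcome = score_trial(trial, result, config$tolerance_ms))
  }
  fold_sizes <- integer(0)
  per_subject <- vector("list", length(subjects))

  for (si in seq_along(subjects)) {
    test_set <- by_subject[[si]]
    if (scheme == "subject_independent") {
      train <- unlist(by_subject[-si], recursive = FALSE)
      fold_sizes <- c(fold_sizes, length(train))
      fit <- if (is.null(detector)) turn_detector(train, location,
                                                  config$criterion, config)
      recs <- lapply(test_set, function(tr) eval_trial(fit, tr))
      cls <- if (length(offsets_ms))
        classify_fold(train, recs, location, offsets_ms, config)
    } else {
      terms <- surface_terms(test_set, location, config)
      recs <- vector("list", length(test_set))
      cls_acc <- NULL
      for (ti in seq_along(test_set)) {
        train <- test_set[-ti]
        fold_sizes <- c(fold_sizes, length(train))
        fit <- if (is.null(detector)) {
          opt <- optimize_thresholds(NULL, location, config, .terms = terms[-ti])
          structure(list(thresholds = opt$thresholds, cost = opt$cost,
                         location = location, config = config,
                         n_trials = length(train)),
                    class = "turn_detector")
        }
        recs[[ti]] <- eval_trial(fit, test_set[[ti]])
        if (length(offsets_ms) && recs[[ti]]$outcome$category == "CD") {
          one <- classify_fold(train, recs[ti], location, offsets_ms, config)
          cls_acc <- if (is.null(cls_acc)) {
            list(direction = rbind(one$direction), amplitude = rbind(one$amplitude))
          } else {
            list(direction = rbind(cls_acc$direction, one$direction),
                 amplitude = rbind(cls_acc$amplitude, one$amplitude))
          }
        }
      }
      cls <- if (length(offsets_ms)) {
        if (is.null(cls_acc)) {
          na <- stats::setNames(rep(NA_real_, length(offsets_ms)), offsets_ms)
          list(direction = na, amplitude = na)
        } else {
          list(direction = colMeans(cls_acc$direction),
               amplitude = colMeans(cls_acc$amplitude))
        }
      }
    }
    rep_s <- aggregate_outcomes(lapply(recs, `[[`, "outcome"))
    rep_s$subject_id <- subjects[si]
    if (length(offsets_ms)) {
      rep_s$direction_accuracy_pct <- cls$direction
      rep_s$amplitude_accuracy_pct <- cls$amplitude
    }
    per_subject[[si]] <- rep_s
  }

  avg <- function(field) {
    v <- vapply(per_subject, function(r) {
      x <- r[[field]]
      if (is.null(x)) NA_real_ else as.numeric(x)
    }, numeric(1))
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  out <- list(cd_pct = avg("cd_pct"), pld_pct = avg("pld_pct"),
              fn_pct = avg("fn_pct"), fp_pct = avg("fp_pct"),
              diff_ms_mean = avg("diff_ms_mean"),
              n_turn_trials = sum(vapply(per_subject, `[[`, 0, "n_turn_trials")),
              n_straight_trials = sum(vapply(per_subject, `[[`, 0, "n_straight_trials")))
  if (length(offsets_ms)) {
    avg_curve <- function(field) {
      m <- do.call(rbind, lapply(per_subject, `[[`, field))
      stats::setNames(colMeans(m, na.rm = TRUE), offsets_ms)
    }
    out$direction_accuracy_pct <- avg_curve("direction_accuracy_pct")
    out$amplitude_accuracy_pct <- avg_curve("amplitude_accuracy_pct")
  }
  out$per_subject <- stats::setNames(per_subject, subjects)
  out$fold_train_sizes <- fold_sizes
  out$scheme <- scheme
  out$location <- location
  out$criterion <- config$criterion
  structure(out, class = "evaluation_report")
}
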