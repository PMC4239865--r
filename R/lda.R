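#' Extract the three-signal feature snapshot at a time point
#'
#' Reads the angular-velocity, magnetometer and orientation channels at the
#' sample nearest `T_ms`. The snapshot taken shortly after a detected turn
#' onset carries the direction (in the signs) and the amplitude (in the
#' magnitudes) of the turn. With `absolute = TRUE` the absolute values are
#' returned, as used for amplitude classification where turn direction is
#' irrelevant.
#'
#' @param signals A zero-referenced [va_signals] object.
#' @param T_ms Snapshot time, ms from trial start (typically detected onset
#'   plus an offset of 0–500 ms).
#' @param absolute Take absolute values (default `FALSE`).
#' @return Named numeric vector `(angular_velocity, mag_heading, angle)`.
#' @export
extract_features <- function(signals, T_ms, absolute = FALSE) {
  stopifnot(inherits(signals, "va_signals"))
  i <- sample_index_at(signals, T_ms, "T_ms")
  f <- c(angular_velocity = signals$angular_velocity[i],
         mag_heading = signals$mag_heading[i],
         angle = signals$angle[i])
  if (absolute) abs(f) else f
}

#' Train a linear discriminant classifier
#'
#' Fits the equal-covariance Gaussian (linear discriminant) model used to
#' classify turn direction and amplitude: per-class mean feature vectors, a
#' pooled within-class covariance, and empirical class priors. Prediction
#' maximises the linear discriminant score
#' \eqn{\delta_c(x) = x^\top \Sigma^{-1}\mu_c - \tfrac12 \mu_c^\top
#' \Sigma^{-1}\mu_c + \log \pi_c}; exact ties are broken to the first label
#' in `class_labels` order. A numerically singular pooled covariance is
#' ridge-regularised by adding `1e-6 * mean(diag)` to the diagonal.
#'
#' @param features Numeric matrix (rows = observations) or list of feature
#'   vectors from [extract_features()].
#' @param labels Class label per row; at least 2 classes with at least 2
#'   observations each.
#' @return An object of class `discriminant_model` with `class_labels`,
#'   `class_means`, `pooled_covariance`, `priors`.
#' @export
#' @examples
#' x <- rbind(matrix(rnorm(60, 2), ncol = 3), matrix(rnorm(60, -2), ncol = 3))
#' m <- train_discriminant(x, rep(c("left", "right"), each = 20))
#' predict(m, c(2, 2, 2))
train_discriminant <- function(features, labels) {
  x <- if (is.list(features) && !is.data.frame(features)) do.call(rbind, features)
       else as.matrix(features)
  storage.mode(x) <- "double"
  labels <- as.character(labels)
  if (nrow(x) != length(labels)) stop("features and labels differ in length")
  classes <- unique(labels)
  if (length(classes) < 2L) stop("training requires at least 2 classes")
  counts <- table(factor(labels, levels = classes))
  if (any(counts < 2L))
    stop("every class needs at least 2 training observations (got ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "), ")")
  p <- ncol(x)
  means <- t(vapply(classes, function(cl) colMeans(x[labels == cl, , drop = FALSE]),
                    numeric(p)))
  centered <- x - means[match(labels, classes), , drop = FALSE]
  pooled <- crossprod(centered) / (nrow(x) - length(classes))
  pooled <- (pooled + t(pooled)) / 2
  if (rcond_psd(pooled) < 1e-12)
    pooled <- pooled + diag(1e-6 * mean(diag(pooled)) + 1e-12, p)
  structure(list(class_labels = classes,
                 class_means = means,
                 pooled_covariance = pooled,
                 priors = as.numeric(counts) / nrow(x)),
            class = "discriminant_model")
}

rcond_psd <- function(m) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) return(0)
  max(min(ev), 0) / max(ev)
}

#' @export
print.discriminant_model <- function(x, ...) {
  cat(sprintf("Linear discriminant model: %d classes (%s), %d features\n",
              length(x$class_labels), paste(x$class_labels, collapse = ", "),
              ncol(x$class_means)))
  invisible(x)
}

# Discriminant scores for a matrix of observations: n x C.
discriminant_scores <- function(model, x) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  si <- solve(model$pooled_covariance)
  w <- si %*% t(model$class_means)                      # p x C
  b <- -0.5 * colSums(t(model$class_means) * w) + log(model$priors)
  sweep(x %*% w, 2, b, `+`)
}

#' Predict class labels with a discriminant model
#'
#' @param object A `discriminant_model`.
#' @param newdata Feature vector or matrix (rows = observations).
#' @param ... Unused.
#' @return Character vector of predicted labels (ties go to the first label
#'   in `class_labels` order).
#' @export
predict.discriminant_model <- function(object, newdata, ...) {
  sc <- discriminant_scores(object, newdata)
  object$class_labels[apply(sc, 1, which.max)]
}

# Features for one trial at onset + offset.
trial_features <- function(trial, location, onset_ms, offset_ms, absolute, config) {
  sig <- zeroed_signals(trial, location, config)
  extract_features(sig, onset_ms + offset_ms, absolute = absolute)
}

#' Train a turn direction or amplitude classifier from labelled trials
#'
#' Extracts the three-signal snapshot at (reference onset + `offset_ms`)
#' from every turn trial and fits a linear discriminant. Direction models
#' use signed features and labels `left`/`right`; amplitude models use
#' absolute features and labels `22`/`45`/`90`. One model is trained per
#' (location, offset) pair.
#'
#' @param database List of [trial_recording] objects (straight trials are
#'   ignored).
#' @param location Sensor location.
#' @param offset_ms Snapshot offset after onset, ms (0–500 in the standard
#'   evaluation).
#' @param task `"direction"` or `"amplitude"`.
#' @param config A [training_config] (for the baseline window).
#' @return A `discriminant_model` with attributes `location`, `offset_ms`,
#'   `absolute`, `task`.
#' @export
train_turn_classifier <- function(database, location, offset_ms = 0,
                                  task = c("direction", "amplitude"),
                                  config = training_config()) {
  task <- match.arg(task)
  absolute <- task == "amplitude"
  turns <- Filter(function(tr) tr$path_label != "straight", database)
  if (!length(turns)) stop("no turn trials in the training database")
  feats <- t(vapply(turns, function(tr)
    trial_features(tr, location, tr$reference_onset_ms, offset_ms, absolute, config),
    numeric(3)))
  labels <- vapply(turns, function(tr) {
    a <- path_amplitude(tr$path_label)
    if (task == "direction") { if (a > 0) "left" else "right" }
    else as.character(abs(a))
  }, "")
  # fixed label order keeps tie-breaking deterministic across training sets
  order_ref <- if (task == "direction") c("left", "right") else c("22", "45", "90")
  model <- train_discriminant(feats, factor(labels, levels = intersect(order_ref, labels)))
  reord <- order(match(model$class_labels, order_ref))
  model$class_labels <- model$class_labels[reord]
  model$class_means <- model$class_means[reord, , drop = FALSE]
  model$priors <- model$priors[reord]
  attr(model, "location") <- location
  attr(model, "offset_ms") <- offset_ms
  attr(model, "absolute") <- absolute
  attr(model, "task") <- task
  model
}

#' Classify turn direction or amplitude for one trial
#'
#' Extracts the snapshot at `onset_ms + offset_ms` (signed for direction,
#' absolute for amplitude) and applies the discriminant model. At
#' prediction time `onset_ms` is the detected onset; at training time the
#' reference onset is used (see [train_turn_classifier()]).
#'
#' @param model A `discriminant_model` from [train_turn_classifier()].
#' @param trial A [trial_recording].
#' @param location Sensor location.
#' @param onset_ms Turn onset, ms.
#' @param offset_ms Snapshot offset after onset, ms.
#' @param config A [training_config].
#' @return `classify_direction()`: `"left"` or `"right"`;
#'   `classify_amplitude()`: 22, 45 or 90 (numeric).
#' @export
classify_direction <- function(model, trial, location, onset_ms, offset_ms = 0,
                               config = training_config()) {
  f <- trial_features(trial, location, onset_ms, offset_ms, FALSE, config)
  predict(model, f)
}

#' @rdname classify_direction
#' @export
classify_amplitude <- function(model, trial, location, onset_ms, offset_ms = 0,
                               config = training_config()) {
  f <- trial_features(trial, location, onset_ms, offset_ms, TRUE, config)
  as.numeric(predict(model, f))
}
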