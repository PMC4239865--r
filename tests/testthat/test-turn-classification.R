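test_that("feature extraction reads the snapshot at the nearest sample", {
  n <- 300
  w <- rep(0, n); m <- rep(0, n); a <- rep(0, n)
  w[201] <- 10; m[201] <- 5; a[201] <- 12     # sample at t = 2000 ms
  sig <- va_signals(w, a, m)
  expect_equal(extract_features(sig, 2000),
               c(angular_velocity = 10, mag_heading = 5, angle = 12))
  w[201] <- -10; m[201] <- -5; a[201] <- -12
  sig <- va_signals(w, a, m)
  expect_equal(extract_features(sig, 2000, absolute = TRUE),
               c(angular_velocity = 10, mag_heading = 5, angle = 12))
  expect_equal(extract_features(sig, 2000),
               c(angular_velocity = -10, mag_heading = -5, angle = -12))
  expect_error(extract_features(sig, 1e6), "outside the recorded series")
})

test_that("the discriminant recovers class structure and breaks ties to the first label", {
  # exactly mirrored classes: means at +/-(50, 20, 30), identical spread
  set.seed(17)
  base <- matrix(rnorm(600), ncol = 3)
  x <- rbind(sweep(base, 2, c(50, 20, 30), `+`),
             sweep(-base, 2, -c(50, 20, 30), `+`))
  labels <- rep(c("left", "right"), each = 200)
  m <- train_discriminant(x, labels)
  expect_identical(m$class_labels, c("left", "right"))
  expect_equal(m$priors, c(0.5, 0.5))
  expect_equal(m$pooled_covariance, t(m$pooled_covariance))
  expect_identical(predict(m, c(50, 20, 30)), "left")
  expect_identical(predict(m, c(-50, -20, -30)), "right")
  # the exact midpoint scores both classes equally: first label wins
  expect_identical(predict(m, c(0, 0, 0)), "left")
})

test_that("discriminant training is invariant to sample order and needs 2 per class", {
  set.seed(23)
  x <- matrix(rnorm(90), ncol = 3)
  labels <- rep(c("a", "b", "c"), each = 10)
  m1 <- train_discriminant(x, labels)
  perm <- sample(30)
  m2 <- train_discriminant(x[perm, ], labels[perm])
  ord <- match(m1$class_labels, m2$class_labels)
  expect_equal(m1$class_means, m2$class_means[ord, ])
  expect_equal(m1$pooled_covariance, m2$pooled_covariance)
  expect_equal(m1$priors, m2$priors[ord])
  expect_error(train_discriminant(x[1:11, ], c(rep("a", 10), "b")),
               "at least 2 training observations")
  expect_error(train_discriminant(x[1:10, ], rep("a", 10)), "at least 2 classes")
})

test_that("predictions agree with an established LDA implementation", {
  set.seed(29)
  mu <- rbind(c(0, 0, 0), c(3, 1, -1), c(-2, 2, 2))
  x <- do.call(rbind, lapply(1:3, function(c)
    sweep(matrix(rnorm(120 * 3), ncol = 3), 2, mu[c, ], `+`)))
  labels <- rep(c("g1", "g2", "g3"), each = 120)
  ours <- train_discriminant(x, labels)
  ref <- MASS::lda(x, grouping = labels)
  test <- matrix(rnorm(900), ncol = 3) * 2
  expect_identical(predict(ours, test),
                   as.character(predict(ref, test)$class))
})

test_that("decision boundaries are linear: few label changes along any segment", {
  set.seed(37)
  x <- rbind(matrix(rnorm(90, 0), ncol = 3),
             matrix(rnorm(90, 3), ncol = 3),
             matrix(rnorm(90, -3), ncol = 3))
  m <- train_discriminant(x, rep(c("a", "b", "c"), each = 30))
  for (i in 1:20) {
    p1 <- rnorm(3, 0, 6); p2 <- rnorm(3, 0, 6)
    tgrid <- seq(0, 1, length.out = 201)
    pts <- outer(1 - tgrid, p1) + outer(tgrid, p2)
    labs <- predict(m, pts)
    expect_lte(length(rle(labs)$lengths), 3)  # at most C-1 = 2 changes
  }
})

test_that("turn classifiers follow the sign convention and mirror exactly", {
  trials <- small_cohort()
  cc <- training_config()
  dir_m <- train_turn_classifier(trials, "upper_back", 200, "direction", cc)
  amp_m <- train_turn_classifier(trials, "upper_back", 200, "amplitude", cc)
  expect_identical(dir_m$class_labels, c("left", "right"))
  expect_identical(amp_m$class_labels, c("22", "45", "90"))

  mirror <- function(tr) {
    tr$signals <- lapply(tr$signals, function(s)
      va_signals(-s$angular_velocity, -s$angle, -s$mag_heading, s$sample_rate))
    tr$path_label <- if (startsWith(tr$path_label, "left"))
      sub("^left", "right", tr$path_label)
    else if (startsWith(tr$path_label, "right"))
      sub("^right", "left", tr$path_label)
    else tr$path_label
    tr
  }
  mirrored <- lapply(trials, mirror)
  dir_mm <- train_turn_classifier(mirrored, "upper_back", 200, "direction", cc)
  amp_mm <- train_turn_classifier(mirrored, "upper_back", 200, "amplitude", cc)
  expect_equal(amp_mm$class_means, amp_m$class_means)  # |features| unchanged

  turns <- which(vapply(trials, `[[`, "", "path_label") != "straight")
  flip <- c(left = "right", right = "left")
  for (i in turns[seq(1, length(turns), by = 3)]) {
    onset <- trials[[i]]$reference_onset_ms
    d0 <- classify_direction(dir_m, trials[[i]], "upper_back", onset, 200, cc)
    d1 <- classify_direction(dir_mm, mirrored[[i]], "upper_back", onset, 200, cc)
    expect_identical(d1, unname(flip[d0]))
    a0 <- classify_amplitude(amp_m, trials[[i]], "upper_back", onset, 200, cc)
    a1 <- classify_amplitude(amp_mm, mirrored[[i]], "upper_back", onset, 200, cc)
    expect_identical(a1, a0)
  }

  # a trial with large positive signals at the snapshot is a left turn
  n <- 1500
  w <- c(rep(0, 1000), rep(80, 500)); th <- cumsum(w) / 100
  left_tr <- make_trial(w, th, "left_90", reference_onset_ms = 10000)
  expect_identical(
    classify_direction(dir_m, left_tr, "upper_back", 10000, 200, cc), "left")
})

test_that("discriminant models survive the JSON round trip", {
  trials <- small_cohort()
  cc <- training_config()
  m <- train_turn_classifier(trials, "upper_back", 100, "amplitude", cc)
  f <- withr::local_tempfile(fileext = ".json")
  write_discriminant_model(m, f)
  back <- read_discriminant_model(f)
  expect_equal(back$class_means, m$class_means, ignore_attr = TRUE)
  expect_equal(back$pooled_covariance, m$pooled_covariance, ignore_attr = TRUE)
  expect_equal(back$priors, m$priors)
  expect_identical(attr(back, "task"), "amplitude")
  tr <- Filter(function(x) x$path_label == "right_90", trials)[[1]]
  expect_identical(
    classify_amplitude(back, tr, "upper_back", tr$reference_onset_ms, 100, cc),
    classify_amplitude(m, tr, "upper_back", tr$reference_onset_ms, 100, cc))
})
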