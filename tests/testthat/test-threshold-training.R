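test_that("the cost function reproduces the four penalty branches exactly", {
  cc <- training_config(criterion = "gyro_only")
  tp <- threshold_pair(58, criterion = "gyro_only")

  expect_warning(z <- detection_cost(tp, list(), "upper_back", cc), "empty")
  expect_equal(z, 0)

  # detection exactly at the reference costs nothing; 600 ms late costs 1
  expect_equal(detection_cost(tp, list(spike_turn_trial(5000, 5000)),
                              "upper_back", cc), 0)
  expect_equal(detection_cost(tp, list(spike_turn_trial(5000, 5600)),
                              "upper_back", cc), 1)
  # exactly at the tolerance boundary: 500 ms is not penalised
  expect_equal(detection_cost(tp, list(spike_turn_trial(5000, 5500)),
                              "upper_back", cc), 0)

  # constructed database: one CD, one late-by-600, one miss, one straight
  # trial with a detection -> 3 errors under unit weights
  db <- list(spike_turn_trial(5000, 5000, id = "CD"),
             spike_turn_trial(5000, 5600, id = "LATE"),
             spike_turn_trial(5000, 5000, peak = 30, id = "FN"),
             flat_straight_trial(peak = 100, id = "FPP"))
  expect_equal(detection_cost(tp, db, "upper_back", cc), 3)
  expect_equal(detection_cost(tp, db, "upper_back", cc),
               oracle_cost(tp, db, "upper_back"))

  # non-unit weights follow the same branches
  cc_w <- training_config(criterion = "gyro_only",
                          error_weights = c(premature_late = 2,
                                            false_negative = 3,
                                            false_positive = 5))
  expect_equal(detection_cost(tp, db, "upper_back", cc_w), 10)
  expect_equal(detection_cost(tp, db, "upper_back", cc_w),
               oracle_cost(tp, db, "upper_back", weights = c(2, 3, 5)))

  expect_error(detection_cost(tp, db, "left_shank", cc), "no signals")
})

test_that("cost agrees with the brute-force oracle on generated trials", {
  trials <- small_cohort()[1:20]
  set.seed(31)
  for (i in 1:8) {
    cr <- sample(c("combined", "gyro_only", "angle_only"), 1)
    tp <- threshold_pair(if (cr == "angle_only") NA else runif(1, 10, 80),
                         if (cr == "gyro_only") NA else runif(1, 3, 30), cr)
    cc <- training_config(criterion = cr)
    expect_equal(detection_cost(tp, trials, "upper_back", cc),
                 oracle_cost(tp, trials, "upper_back"))
  }
})

test_that("the fast cost surface equals the per-trial cost loop", {
  trials <- small_cohort()[1:20]
  cc <- training_config(criterion = "combined")
  surf <- turndetect:::cost_surface(trials, "upper_back", cc)
  set.seed(41)
  g <- runif(12, 5, 120); a <- runif(12, 2, 60)
  fast <- surf(g, a)
  slow <- vapply(seq_along(g), function(i)
    detection_cost(threshold_pair(g[i], a[i]), trials, "upper_back", cc),
    numeric(1))
  expect_equal(fast, slow)
})

test_that("increasing the tolerance never increases the cost", {
  trials <- small_cohort()[1:25]
  tp <- threshold_pair(40, 12)
  costs <- vapply(c(100, 250, 500, 750, 1000, 2000), function(tol)
    detection_cost(tp, trials, "upper_back", training_config(tolerance_ms = tol)),
    numeric(1))
  expect_true(all(diff(costs) <= 0))
})

test_that("optimisation finds the zero-cost threshold band in a separable database", {
  # turns jump to 81 deg/s at the reference onset; straight trials peak at
  # exactly 30 -> every threshold in [30, 81) has zero cost
  db <- c(lapply(1:3, function(i) spike_turn_trial(5000, 5000, peak = 81,
                                                   id = paste0("T", i))),
          lapply(4:6, function(i) flat_straight_trial(peak = 30,
                                                      id = paste0("T", i))))
  cc <- training_config(criterion = "gyro_only", optimizer_seed = 2)
  fit <- optimize_thresholds(db, "upper_back", cc)
  expect_equal(fit$cost, 0)
  expect_gt(fit$thresholds$gyr_thresh, 29.99)
  expect_lt(fit$thresholds$gyr_thresh, 81)
  expect_equal(detection_cost(fit$thresholds, db, "upper_back", cc), 0)

  # a grid search confirms the zero-cost region independently
  g <- grid_search_thresholds(db, "upper_back", cc)
  expect_equal(g$cost, 0)
})

coef_pair <- function(fit) c(fit$thresholds$gyr_thresh, fit$thresholds$angle_thresh,
                             fit$cost)

test_that("optimisation is deterministic and never worse than the reference grid", {
  trials <- small_cohort()
  for (cr in c("combined", "gyro_only", "angle_only")) {
    cc <- training_config(criterion = cr, optimizer_seed = 5)
    f1 <- optimize_thresholds(trials, "upper_back", cc)
    f2 <- optimize_thresholds(trials, "upper_back", cc)
    expect_identical(coef_pair(f1), coef_pair(f2))
    g <- grid_search_thresholds(trials, "upper_back", cc)
    expect_lte(f1$cost, g$cost)
  }
})

test_that("zero error weights make every threshold free", {
  cc <- training_config(criterion = "combined",
                        error_weights = c(premature_late = 0,
                                          false_negative = 0,
                                          false_positive = 0))
  fit <- optimize_thresholds(small_cohort()[1:10], "upper_back", cc)
  expect_equal(fit$cost, 0)
})

test_that("the fitted detector exposes the modelling interface", {
  trials <- small_cohort()
  fit <- turn_detector(trials, "upper_back")
  expect_s3_class(fit, "turn_detector")
  expect_named(coef(fit), c("gyr_thresh", "angle_thresh"))
  expect_output(print(fit), "combined criterion")
  res <- predict(fit, trials[[1]])
  expect_s3_class(res, "detection_result")
  both <- predict(fit, trials[1:3])
  expect_length(both, 3)
  # the training cost matches an independent re-count at the fitted point
  expect_equal(fit$cost,
               oracle_cost(fit$thresholds, trials, "upper_back"))
})
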