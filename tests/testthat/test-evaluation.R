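det_result <- function(detected, onset_ms = NULL, trigger = "gyro")
  turndetect:::detection_result(detected, onset_ms, trigger)

test_that("trial outcomes follow the tolerance boundary", {
  turn <- make_trial(rep(0, 1200), rep(0, 1200), "left_45",
                     reference_onset_ms = 5000)
  straight <- make_trial(rep(0, 1200), rep(0, 1200), "straight")

  expect_identical(score_trial(turn, det_result(TRUE, 5499))$category, "CD")
  expect_identical(score_trial(turn, det_result(TRUE, 5500))$category, "CD")
  expect_identical(score_trial(turn, det_result(TRUE, 5501))$category, "PLD")
  expect_identical(score_trial(turn, det_result(TRUE, 4400))$category, "PLD")
  expect_identical(score_trial(turn, det_result(FALSE))$category, "FN")
  expect_identical(score_trial(straight, det_result(TRUE, 3000))$category, "FP")
  expect_identical(score_trial(straight, det_result(FALSE))$category, "TN")
  expect_equal(score_trial(turn, det_result(TRUE, 5499))$diff_ms, 499)
  expect_null(score_trial(turn, det_result(FALSE))$diff_ms)
})

test_that("aggregation uses the documented denominators", {
  out <- c(lapply(c(100, -200, 0), function(d) score_trial(
             make_trial(rep(0, 1200), rep(0, 1200), "left_22",
                        reference_onset_ms = 5000),
             det_result(TRUE, 5000 + d))),
           lapply(c(900, -1200), function(d) score_trial(
             make_trial(rep(0, 1200), rep(0, 1200), "left_22",
                        reference_onset_ms = 5000),
             det_result(TRUE, 5000 + d))),
           list(score_trial(make_trial(rep(0, 1200), rep(0, 1200), "left_22",
                                       reference_onset_ms = 5000),
                            det_result(FALSE)),
                score_trial(make_trial(rep(0, 1200), rep(0, 1200), "straight"),
                            det_result(TRUE, 3000)),
                score_trial(make_trial(rep(0, 1200), rep(0, 1200), "straight"),
                            det_result(FALSE))))
  # 3 CD, 2 PLD, 1 FN over 6 turn trials; 1 FP over 2 straight trials
  rep <- aggregate_outcomes(out)
  expect_equal(rep$cd_pct, 50)
  expect_equal(rep$pld_pct, 100 / 3)
  expect_equal(rep$fn_pct, 100 / 6)
  expect_equal(rep$fp_pct, 50)
  expect_equal(rep$cd_pct + rep$pld_pct + rep$fn_pct, 100, tolerance = 1e-9)
  expect_equal(rep$diff_ms_mean, mean(c(100, -200, 0, 900, -1200)))
  expect_equal(rep$n_turn_trials, 6)
  expect_equal(rep$n_straight_trials, 2)
  expect_error(aggregate_outcomes(list()), "empty")

  # all-correct degenerate case
  allcd <- aggregate_outcomes(out[1:3])
  expect_equal(allcd$cd_pct, 100)
  expect_equal(allcd$pld_pct, 0)
  expect_equal(allcd$fn_pct, 0)
  expect_true(is.na(allcd$fp_pct))  # no straight trial -> FP absent
})

test_that("amplitude subsetting keeps straight trials and filters turns", {
  session <- generate_session(gait_config(seed = 3, locations = "upper_back"), 1)
  expect_length(session, 49)
  expect_length(subset_by_amplitude(session, c(22, 45, 90)), 49)
  expect_length(subset_by_amplitude(session, c(45, 90)), 35)  # 7 straight + 4x7
  k90 <- subset_by_amplitude(session, 90)
  expect_length(k90, 21)
  expect_setequal(unique(vapply(k90, `[[`, "", "path_label")),
                  c("straight", "left_90", "right_90"))
  expect_error(subset_by_amplitude(session, integer(0)), "non-empty subset")
  expect_error(subset_by_amplitude(session, 30), "non-empty subset")
})

test_that("injected oracle detectors bound the evaluation metrics", {
  cohort <- small_cohort()
  perfect <- function(trial) {
    if (trial$path_label == "straight") det_result(FALSE)
    else det_result(TRUE, trial$reference_onset_ms)
  }
  never <- function(trial) det_result(FALSE)
  for (scheme in c("subject_independent", "within_subject")) {
    r <- crossvalidate(cohort, scheme, "upper_back", training_config(),
                       offsets_ms = NULL, detector = perfect)
    expect_equal(r$cd_pct, 100)
    expect_equal(r$fp_pct, 0)
    expect_equal(r$diff_ms_mean, 0)
    r2 <- crossvalidate(cohort, scheme, "upper_back", training_config(),
                        offsets_ms = NULL, detector = never)
    expect_equal(r2$fn_pct, 100)
    expect_equal(r2$fp_pct, 0)
  }
})

test_that("crossvalidation fold sizes and preconditions follow the schemes", {
  cohort <- small_cohort()   # 3 subjects x 14 trials
  si <- crossvalidate(cohort, "subject_independent", "upper_back",
                      training_config(), offsets_ms = NULL)
  expect_true(all(si$fold_train_sizes == 28))
  expect_equal(si$cd_pct + si$pld_pct + si$fn_pct, 100, tolerance = 1e-9)

  ws <- crossvalidate(cohort[1:28], "within_subject", "upper_back",
                      training_config(), offsets_ms = NULL)
  expect_true(all(ws$fold_train_sizes == 13))
  expect_length(ws$fold_train_sizes, 28)
  expect_equal(ws$cd_pct + ws$pld_pct + ws$fn_pct, 100, tolerance = 1e-9)

  one_subject <- Filter(function(tr) tr$subject_id == "S01", cohort)
  expect_error(crossvalidate(one_subject, "subject_independent", "upper_back"),
               ">= 2 subjects")
  expect_error(crossvalidate(cohort[c(1, 15)], "within_subject", "upper_back"),
               ">= 2 trials")
})

test_that("reports average per subject, not per trial", {
  # two subjects with different trial mixes: the pooled rate would be
  # weighted, the subject average is not
  turn <- function(s) make_trial(rep(0, 1200), rep(0, 1200), "left_22",
                                 reference_onset_ms = 5000, subject_id = s)
  det <- function(trial) {
    if (trial$subject_id == "A") det_result(TRUE, trial$reference_onset_ms)
    else det_result(FALSE)
  }
  # subject A: all detected; subject B: all missed -> unweighted mean CD 50
  trials <- c(lapply(1:6, function(i) {
    t <- turn("A"); t$trial_id <- paste0("A", i); t
  }), lapply(1:2, function(i) {
    t <- turn("B"); t$trial_id <- paste0("B", i); t
  }))
  r <- crossvalidate(trials, "within_subject", "upper_back", training_config(),
                     offsets_ms = NULL, detector = det)
  expect_equal(r$cd_pct, 50)  # (100 + 0) / 2, not 6/8
  expect_equal(r$per_subject$A$cd_pct, 100)
  expect_equal(r$per_subject$B$fn_pct, 100)
})

test_that("report rendering yields the expected table shapes", {
  cohort <- small_cohort()
  r1 <- crossvalidate(cohort, "subject_independent", "upper_back",
                      training_config(), offsets_ms = c(0, 100))
  r2 <- crossvalidate(cohort, "subject_independent", "left_foot",
                      training_config(), offsets_ms = c(0, 100))
  tab <- render_report(list(r1, r2), "onset_table")
  expect_equal(nrow(tab), 2)
  expect_named(tab, c("scheme", "location", "criterion", "cd_pct", "pld_pct",
                      "fn_pct", "fp_pct", "diff_ms"))
  curves <- render_report(list(r1, r2), "accuracy_curves")
  expect_equal(nrow(curves), 4)  # 2 reports x 2 offsets
  expect_error(render_report(list(), "onset_table"), "at least one")
})
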