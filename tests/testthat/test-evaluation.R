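test_that("confusion counts match hand enumeration", {
  y_true <- c("a", "a", "a", "b", "b", "b")
  y_pred <- c("a", "a", "b", "b", "b", "b")
  m <- confusion(y_true, y_pred, classes = c("a", "b"))
  expect_identical(unclass(m)[, ],
                   matrix(c(2L, 0L, 1L, 3L), 2,
                          dimnames = list(truth = c("a", "b"),
                                          predicted = c("a", "b"))))
  expect_identical(sum(m), 6L)
  # identical vectors give a diagonal matrix
  md <- confusion(y_true, y_true, c("a", "b"))
  expect_identical(sum(md) - sum(diag(md)), 0L)
  expect_error(confusion(y_true, c(y_pred[-6], "zz"), c("a", "b")),
               "outside the class list")
})

test_that("a perfect classifier scores 1 everywhere", {
  m <- confusion(rep(letters[1:3], 5:7), rep(letters[1:3], 5:7),
                 letters[1:3])
  rep_ <- metrics_from_confusion(m)
  expect_equal(rep_$accuracy, 1)
  expect_true(all(rep_$per_class$f1 == 1))
  expect_equal(unname(rep_$macro), rep(1, 3))
  expect_error(metrics_from_confusion(matrix(0, 2, 2)), "empty")
})

test_that("weighted recall equals accuracy and macro lies within class range", {
  set.seed(10)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    n <- 300
    cls <- letters[1:k]
    y <- sample(cls, n, TRUE)
    p <- ifelse(stats::runif(n) < 0.6, y, sample(cls, n, TRUE))
    rep_ <- metrics_from_confusion(confusion(y, p, cls))
    expect_equal(unname(rep_$weighted["sensitivity"]), rep_$accuracy,
                 tolerance = 1e-12)
    for (met in c("precision", "sensitivity", "f1")) {
      expect_lte(rep_$macro[met], max(rep_$per_class[[met]]) + 1e-12)
      expect_gte(rep_$macro[met], min(rep_$per_class[[met]]) - 1e-12)
    }
  }
})

test_that("display rounding is half-up to 3 decimals", {
  expect_equal(round_half_up(0.8535, 3), 0.854)
  expect_equal(round_half_up(0.8534999, 3), 0.853)
  expect_equal(round_half_up(0.7605, 3), 0.761)
})

test_that("a never-predicted class gets zero precision and a flag", {
  m <- confusion(c("a", "a", "b"), c("b", "b", "b"), c("a", "b"))
  rep_ <- metrics_from_confusion(m)
  expect_identical(rep_$per_class$precision[1], 0)
  expect_true(rep_$per_class$never_predicted[1])
})

test_that("bootstrap intervals behave at the closed-form corners", {
  # perfect predictions: degenerate [1, 1] interval with a warning
  y <- rep(c("a", "b"), 50)
  expect_warning(ci <- bootstrap_ci(y, y, "accuracy", n_boot = 200,
                                    seed = 1), "degenerate")
  expect_identical(c(ci$lower, ci$upper), c(1, 1))
  # chance-level predictor on balanced binary truth, n = 1000 (accuracy
  # exactly 0.5): CI covers 0.5 with width about 2 * 1.96 * sqrt(0.25/1000)
  set.seed(3)
  yt <- sample(c("a", "b"), 1000, TRUE)
  yp <- c(yt[1:500], ifelse(yt[501:1000] == "a", "b", "a"))
  ci <- bootstrap_ci(yt, yp, "accuracy", n_boot = 2000, seed = 4)
  expect_lte(ci$lower, 0.5)
  expect_gte(ci$upper, 0.5)
  expect_lt(abs((ci$upper - ci$lower) - 0.062), 0.02)
  # deterministic per seed; estimate always inside
  ci2 <- bootstrap_ci(yt, yp, "accuracy", n_boot = 2000, seed = 4)
  expect_identical(ci, ci2)
  expect_true(ci$lower <= ci$estimate && ci$estimate <= ci$upper)
})

test_that("bootstrap intervals cover a known accuracy most of the time", {
  set.seed(7)
  true_acc <- 0.8
  hits <- 0
  for (r in 1:100) {
    y <- sample(c("a", "b"), 200, TRUE)
    p <- ifelse(stats::runif(200) < true_acc, y,
                ifelse(y == "a", "b", "a"))
    ci <- bootstrap_ci(y, p, "accuracy", n_boot = 400, seed = r)
    hits <- hits + (ci$lower <= true_acc && true_acc <= ci$upper)
  }
  expect_gte(hits, 90)
})

test_that("patient split balances classes without splitting patients", {
  cohort <- clean_cohort(n = 2000, seed = 61)
  sp <- patient_split(cohort, split_plan(test_frac = 0.2, seed = 5))
  pat <- vapply(cohort, `[[`, "", "patient_id")
  expect_length(intersect(pat[sp$train], pat[sp$test]), 0L)
  frac <- length(sp$test) / length(cohort)
  expect_lt(abs(frac - 0.2), 0.03)
  truth <- cohort_truth(cohort)
  for (cl in unique(truth)) {
    cl_frac <- sum(truth[sp$test] == cl) / sum(truth == cl)
    expect_lt(abs(cl_frac - 0.2), 0.03 + 1e-9, label = cl)
  }
  # deterministic per seed
  expect_identical(sp, patient_split(cohort, split_plan(seed = 5)))
  # a single patient cannot be split
  one <- cohort[pat == pat[1]]
  expect_warning(sp1 <- patient_split(one, split_plan()), "single patient")
  expect_length(sp1$test, 0L)
})

test_that("subgroup reports partition the cohort and flag small levels", {
  cohort <- clean_cohort(n = 300, seed = 62)
  preds <- cohort_truth(cohort)  # evaluate the identity predictor
  rep_ <- subgroup_report(cohort, preds, "manufacturer", ci = FALSE)
  expect_identical(sum(rep_$n), 300L)
  expect_true(all(rep_$accuracy == 1))
  expect_true(all(rep_$unstable == (rep_$n < 30)))
  # single-level factor equals the global report
  rep_f <- subgroup_report(cohort, preds, "field_strength", ci = FALSE)
  expect_true(all(rep_f$accuracy == 1))
  expect_error(subgroup_report(cohort, preds, "sequence"), "arg")
})
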