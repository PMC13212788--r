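test_that("the weighted AUC equals the quadratic-time oracle, ties included", {
  set.seed(71)
  n <- 300L
  scores <- round(rnorm(n), 1)          # rounding forces ties
  labels <- rbinom(n, 1, 0.3)
  weights <- runif(n, 0.2, 3)
  r <- weighted_roc_auc(scores, labels, weights)
  expect_equal(r$auc, auc_oracle(scores, labels, weights), tolerance = 1e-12)
  expect_equal(r$n_pos_eff, sum(weights[labels > 0]))
  expect_equal(r$n_neg_eff, sum(weights[labels == 0]))
  # unweighted case agrees with the classic Mann-Whitney statistic
  r1 <- weighted_roc_auc(scores, labels)
  expect_equal(r1$auc, auc_oracle(scores, labels, rep(1, n)), tolerance = 1e-12)
})

test_that("the AUC is invariant to monotone score transformations", {
  set.seed(72)
  scores <- rnorm(120); labels <- rbinom(120, 1, 0.4); w <- runif(120, 0.5, 2)
  a0 <- weighted_roc_auc(scores, labels, w)$auc
  expect_identical(weighted_roc_auc(3.7 * scores + 11, labels, w)$auc, a0)
  expect_equal(weighted_roc_auc(exp(scores), labels, w)$auc, a0,
               tolerance = 1e-12)
  # label inversion complements the AUC
  expect_equal(weighted_roc_auc(-scores, labels, w)$auc, 1 - a0,
               tolerance = 1e-12)
})

test_that("constant scores give exactly chance performance", {
  r <- weighted_roc_auc(rep(2, 50), rep(c(0, 1), 25), runif(50, 0.5, 1))
  expect_identical(r$auc, 0.5)
})

test_that("degenerate inputs are rejected", {
  expect_error(weighted_roc_auc(1:5, rep(1, 5)), "both classes")
  expect_error(weighted_roc_auc(1:4, c(0, 1, 0, 1), c(1, -1, 1, 1)))
})

test_that("the Youden point maximises sensitivity + specificity - 1", {
  set.seed(73)
  scores <- c(rnorm(60, 1), rnorm(60, -1))
  labels <- rep(c(1, 0), each = 60)
  r <- weighted_roc_auc(scores, labels)
  yp <- youden_point(r)
  expect_equal(yp$J, max(r$curve$sens + r$curve$spec - 1), tolerance = 1e-12)
  expect_gt(yp$J, 0.3)
  expect_lte(yp$sensitivity, 1); expect_lte(yp$specificity, 1)
})

test_that("zone stratification reports NA for single-class zones", {
  set.seed(74)
  n <- 200L
  scores <- runif(n); labels <- rbinom(n, 1, 0.3); w <- rep(1, n)
  pz <- c(rep(TRUE, 100), rep(FALSE, 100))
  tz <- !pz
  labels[tz] <- 0     # transition zone has no positive voxel
  tb <- zone_stratified_eval(scores, labels, w, pz, tz)
  expect_identical(tb$zone, c("whole", "pz", "tz"))
  expect_true(is.finite(tb$auc[tb$zone == "whole"]))
  expect_true(is.na(tb$auc[tb$zone == "tz"]))
})

test_that("repeated-CV aggregation matches the normal-approximation CI", {
  a <- c(0.8, 0.85, 0.9, 0.75)
  ag <- repeated_cv_aggregate(a)
  expect_equal(ag$mean, mean(a))
  expect_equal(ag$ci_high - ag$ci_low, 2 * 1.96 * sd(a) / 2, tolerance = 1e-12)
  expect_error(repeated_cv_aggregate(0.8), "length")
})

test_that("the weighted AUC agrees with pROC on unweighted data", {
  skip_if_not_installed("pROC")
  set.seed(75)
  scores <- rnorm(250); labels <- rbinom(250, 1, 0.4)
  a <- weighted_roc_auc(scores, labels)$auc
  b <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                      direction = "<")))
  expect_equal(a, b, tolerance = 1e-12)
})
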