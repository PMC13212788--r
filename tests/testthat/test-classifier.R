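test_that("the default architecture lands in the expected parameter budget", {
  model <- build_model(architecture_spec(), seed = 1L)
  n <- count_parameters(model)
  expect_identical(n, 46941L)
  # a misconfigured width triggers the budget warning
  expect_warning(build_model(architecture_spec(conv_widths = c(4L, 4L, 4L))),
                 "outside")
})

test_that("model initialisation is deterministic under the seed", {
  m1 <- build_model(seed = 7L)
  m2 <- build_model(seed = 7L)
  m3 <- build_model(seed = 8L)
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params, m3$params))
})

test_that("fold assignment partitions patients and balances lesion burden", {
  set.seed(61)
  sizes <- c(rep(0, 10), runif(25, 0.1, 10))
  ids <- sprintf("p%02d", seq_along(sizes))
  plan <- make_folds(ids, sizes, k = 5L, seed = 3L)
  expect_setequal(plan$patient, ids)
  expect_true(all(plan$fold %in% 1:5))
  # every fold receives at least one no-csPCa and one csPCa patient
  tab <- table(plan$fold, plan$subgroup != "none")
  expect_true(all(tab > 0))
  # subgroup counts differ by at most one across folds
  for (s in unique(plan$subgroup)) {
    cnt <- table(factor(plan$fold[plan$subgroup == s], levels = 1:5))
    expect_lte(max(cnt) - min(cnt), 1)
  }
  expect_identical(make_folds(ids, sizes, k = 5L, seed = 3L), plan)
})

test_that("batch sampling rebalances classes exactly", {
  set.seed(62)
  labels <- c(rep(1, 40), rep(0, 4000))
  batches <- sample_batches(labels, positive_fraction = 0.5,
                            batch_size = 16L, seed = 4L)
  expect_equal(length(batches), 40 %/% 8)
  for (b in batches) {
    expect_equal(length(b), 16L)
    expect_equal(sum(labels[b]), 8)
  }
  # each positive is used exactly once per epoch (single pass over minority)
  expect_setequal(unlist(lapply(batches, function(b) b[labels[b] > 0])),
                  which(labels > 0))
})

test_that("augmentation preserves shape and respects zero settings", {
  x <- matrix(rnorm(27 * 4 * 3), 27 * 4, 3)
  expect_identical(augment(x, 0, 0), x)
  xa <- augment(x, 0.1, 0.1, n_batch = 4L, seed = 5L)
  expect_identical(dim(xa), dim(x))
  expect_false(identical(xa, x))
  expect_identical(augment(x, 0.1, 0.1, n_batch = 4L, seed = 5L), xa)
  # pure offsets are constant within each sample-feature block
  xo <- augment(x, 0, 0.2, n_batch = 4L, seed = 6L)
  delta <- xo - x
  blk <- delta[1:27, 1]
  expect_equal(max(blk) - min(blk), 0, tolerance = 1e-12)
})

test_that("forward feature selection stops at an epsilon-insufficient gain", {
  # score of a set = best achievable with features "a" and "b"; "c" adds noise
  score <- function(set) {
    0.5 + 0.2 * ("a" %in% set) + 0.1 * ("b" %in% set) + 1e-4 * ("c" %in% set)
  }
  sel <- forward_feature_selection(c("a", "b", "c"),
                                   eval_fn = function(set) score(set),
                                   epsilon = 0.001)
  expect_identical(sel$selected, c("a", "b"))
  expect_equal(max(sel$trace$auc[sel$trace$accepted]), 0.8)
  expect_false(sel$trace$accepted[nrow(sel$trace)])
})
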