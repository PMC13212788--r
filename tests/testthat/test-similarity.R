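test_that("quantile binning matches per-row ranking", {
  set.seed(2)
  Y <- matrix(rnorm(40 * 25), 40)
  B <- 8L
  bx <- mpuscad:::quantile_bins(Y, B)
  ref <- t(apply(Y, 1, function(y) {
    b <- ceiling(rank(y, ties.method = "first") * B / length(y))
    pmin(pmax(b, 1), B)
  }))
  expect_identical(as.vector(bx), as.integer(ref))
  expect_true(all(bx >= 1L & bx <= B))
  # occupancy is balanced: each bin holds floor/ceiling of n/B samples
  tab <- apply(bx, 1, tabulate, nbins = B)
  expect_true(all(abs(tab - 25 / B) < 1))
})

test_that("mutual information is maximal for a copy and near zero when independent", {
  set.seed(3)
  B <- 8L
  n <- 4000L
  x <- matrix(rnorm(n), 1)
  bx <- mpuscad:::quantile_bins(x, B)
  mi_self <- mpuscad:::pair_mutual_information(bx, bx, B)
  expect_equal(mi_self, log2(B), tolerance = 1e-6)
  y <- matrix(rnorm(n), 1)
  by <- mpuscad:::quantile_bins(y, B)
  mi_ind <- mpuscad:::pair_mutual_information(bx, by, B)
  bias_bound <- (B - 1)^2 / (2 * n * log(2))
  expect_lt(mi_ind, 3 * bias_bound)
  expect_gte(mi_ind, 0)
})

test_that("identical neighbourhood TICs give perfect correlation and coherence", {
  d <- c(7L, 7L, 7L)
  t <- seq(0, 59)
  base <- sin(2 * pi * t / 20) + 2
  data <- array(rep(base, each = prod(d)), dim = c(d, length(t)))
  tv <- tic_volume(data, t, voxel_size_mm = 1)
  sm <- suppressWarnings(similarity_maps(tv, ring_radius_mm = 2))
  expect_equal(sm$corr_time[4, 4, 4], 1, tolerance = 1e-9)
  expect_equal(sm$coh_freq[4, 4, 4], 1, tolerance = 1e-6)
  expect_gte(sm$mi[4, 4, 4], 0)
})

test_that("correlation map separates coherent from incoherent regions", {
  set.seed(7)
  d <- c(10L, 7L, 7L)
  t <- seq(0, 59)
  base <- exp(-(t - 25)^2 / 200)
  data <- array(rnorm(prod(d) * length(t), sd = 1), dim = c(d, length(t)))
  # coherent half: shared waveform with small noise
  for (i in 1:5) data[i, , , ] <- rep(base, each = 7 * 7) +
    rnorm(7 * 7 * length(t), sd = 0.01)
  tv <- tic_volume(data, t, voxel_size_mm = 1)
  cm <- tic_correlation_map(tv, ring_radius_mm = 2)
  expect_gt(mean(cm[2:4, 3:5, 3:5], na.rm = TRUE),
            mean(cm[7:9, 3:5, 3:5], na.rm = TRUE) + 0.5)
})
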