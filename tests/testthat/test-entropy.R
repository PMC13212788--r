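test_that("arrival times are recovered from shifted bolus curves", {
  t <- seq(0, 30, by = 0.1)
  d <- c(3L, 2L, 1L)
  shifts <- array(seq(2, 12, length.out = prod(d)), dim = d)
  data <- array(0, dim = c(d, length(t)))
  for (i in seq_len(prod(d))) {
    data[((i - 1) %% 3) + 1, (((i - 1) %/% 3) %% 2) + 1, 1, ] <-
      exp(-(t - shifts[i] - 4)^2 / 4)
  }
  tau <- arrival_time_map(tic_volume(data, t), threshold_fraction = 0.5)
  # half-peak crossing of a Gaussian of sd sqrt(2) occurs sqrt(4 log 2)/sqrt(2)
  # before its centre: the map must preserve all pairwise delays
  expect_equal(as.vector(tau) - tau[1],
               as.vector(shifts) - shifts[1], tolerance = 0.05)
})

test_that("a planar arrival-time ramp yields the exact velocity", {
  d <- c(9L, 9L, 9L)
  co <- mpuscad:::coord_arrays(d, 1, c(0, 0, 0))
  # slowness (0.02, 0.01, 0) s/mm -> speed 1/|s| = 44.72 mm/s
  tau <- 5 + 0.02 * co$x + 0.01 * co$y
  f <- velocity_field_from_delays(tau, window_vox = 5L, voxel_size_mm = 1)
  ctr <- f$valid[5, 5, 5]
  expect_true(ctr)
  expect_equal(f$sx[5, 5, 5], 0.02, tolerance = 1e-9)
  expect_equal(f$sy[5, 5, 5], 0.01, tolerance = 1e-9)
  expect_equal(f$v_mag[5, 5, 5], 1 / sqrt(0.02^2 + 0.01^2), tolerance = 1e-6)
  # velocity points opposite the arrival-time gradient
  expect_lt(f$dx[5, 5, 5], 0)
  # direction is a unit vector
  expect_equal(f$dx[5, 5, 5]^2 + f$dy[5, 5, 5]^2 + f$dz[5, 5, 5]^2, 1,
               tolerance = 1e-12)
})

test_that("sub-resolution gradients are invalidated", {
  d <- c(9L, 9L, 9L)
  tau <- array(5, dim = d)  # flat arrival: infinitely fast apparent flow
  f <- velocity_field_from_delays(tau, voxel_size_mm = 1)
  expect_false(any(f$valid))
  expect_true(all(is.na(f$v_mag)))
})

test_that("a uniform direction field has exactly zero entropy", {
  d <- c(9L, 9L, 9L)
  f <- synthetic_direction_field(rep(0.3, prod(d)), d)
  em <- velocity_entropy_maps(f, window_vox = 5L)
  ctr <- em$H[3:7, 3:7, 3:7]
  expect_true(all(is.finite(ctr)))
  expect_identical(unique(as.vector(ctr)), 0)
  expect_identical(unique(as.vector(em$H_cond[3:7, 3:7, 3:7])), 0)
})

test_that("conditional entropy never exceeds marginal entropy", {
  set.seed(21)
  d <- c(9L, 9L, 9L)
  f <- synthetic_direction_field(runif(prod(d), -pi, pi), d)
  em <- velocity_entropy_maps(f, window_vox = 5L, azimuth_bins = 8L,
                              elevation_bins = 1L)
  has <- is.finite(em$H)
  expect_gt(sum(has), 100)
  expect_true(all(em$H_cond[has] <= em$H[has] + 1e-12))
  expect_true(all(em$H[has] >= 0))
  expect_true(all(em$H[has] <= 3 + 1e-12))  # log2(8) bound
})

test_that("uniform random directions approach the maximal 3-bit entropy", {
  set.seed(22)
  d <- c(11L, 11L, 11L)
  f <- synthetic_direction_field(runif(prod(d), -pi, pi), d)
  em <- velocity_entropy_maps(f, window_vox = 11L, azimuth_bins = 8L,
                              elevation_bins = 1L)
  h_ctr <- em$H[6, 6, 6]   # the only clip-free 11^3 (>= 1000 sample) window
  expect_lt(abs(h_ctr - 3) / 3, 0.02)
})
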