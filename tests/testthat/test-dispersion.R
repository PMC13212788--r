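test_that("the estimator recovers velocity and diffusion of an analytic bolus", {
  sim <- simulate_dispersion_field(grid_shape = c(21L, 21L, 21L),
                                   voxel_size_mm = 1, v = c(1.5, -0.8, 0.4),
                                   D = 0.8)
  disp <- estimate_convective_dispersion(
    sim$ticvol, time_window_s = range(sim$ticvol$time_s))
  core <- 8:14
  sel <- array(FALSE, dim = c(21, 21, 21)); sel[core, core, core] <- TRUE
  sel <- sel & disp$valid
  expect_gt(sum(sel), 100)
  expect_lt(median(abs(disp$D[sel] - 0.8) / 0.8), 0.05)
  expect_lt(median(abs(disp$vx[sel] - 1.5) / 1.5), 0.05)
  expect_lt(median(abs(disp$vy[sel] + 0.8) / 0.8), 0.05)
  vm <- sqrt(1.5^2 + 0.8^2 + 0.4^2)
  expect_lt(median(abs(disp$v_mag[sel] - vm) / vm), 0.05)
})

test_that("pure diffusion yields near-zero velocity", {
  sim <- simulate_dispersion_field(v = c(0, 0, 0), D = 1)
  disp <- estimate_convective_dispersion(
    sim$ticvol, time_window_s = range(sim$ticvol$time_s))
  core <- 8:14
  sel <- array(FALSE, dim = c(21, 21, 21)); sel[core, core, core] <- TRUE
  sel <- sel & disp$valid
  expect_lt(median(disp$v_mag[sel]), 0.05)
  expect_lt(median(abs(disp$D[sel] - 1)), 0.05)
})

test_that("negative fitted diffusion and bad windows are rejected", {
  expect_error(estimate_convective_dispersion(
    simulate_dispersion_field()$ticvol, window_vox = 4L), "odd")
  sim <- simulate_dispersion_field()
  expect_error(estimate_convective_dispersion(
    sim$ticvol, time_window_s = c(100, 101)), "fewer than 3")
  # a volume of pure noise yields mostly invalid voxels
  set.seed(9)
  d <- c(9L, 9L, 9L)
  noise <- array(rnorm(prod(d) * 12), dim = c(d, 12L))
  tv <- tic_volume(noise, seq(0, 11) * 0.5)
  nd <- estimate_convective_dispersion(tv, time_window_s = c(0, 5.5))
  expect_true(all(nd$D[nd$valid] >= 0))
  expect_true(all(is.na(nd$D[!nd$valid])))
})
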