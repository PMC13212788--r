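test_that("Loupas autocorrelation inverts the IQ phase progression exactly", {
  set.seed(31)
  prf <- 1e4; fc <- 6e6; c_us <- 1540
  v <- array(runif(5 * 4 * 10, -0.05, 0.05), dim = c(5, 4, 10))
  iq <- synthesize_iq(v, prf, fc, c_us)
  est <- loupas_velocity(iq, prf, fc, c_us)
  # frame n of the estimate equals the synthesized velocity at frame n
  expect_equal(as.vector(est), as.vector(v[, , 1:9]), tolerance = 1e-12)
  # closed form: v = c * prf * dphi / (4 pi f_c)
  dphi <- 4 * pi * fc * v[1, 1, 1] / (c_us * prf)
  expect_equal(est[1, 1, 1], c_us * prf * dphi / (4 * pi * fc),
               tolerance = 1e-12)
})

test_that("aliasing near the Nyquist velocity is flagged", {
  prf <- 1e3; fc <- 6e6; c_us <- 1540
  v_nyq <- c_us * prf / (4 * fc)        # phase pi
  v <- array(0.95 * v_nyq, dim = c(2, 1, 3))
  expect_warning(est <- loupas_velocity(synthesize_iq(v, prf, fc, c_us),
                                        prf, fc, c_us), "aliased")
  expect_true(all(attr(est, "aliasing")))
})

test_that("time-of-flight recovers a constant shear-wave speed and E = 3 c^2", {
  pl <- constant_speed_plane(c_mps = 2)
  em <- sws_crosscorr(pl)
  sws <- em$sws[is.finite(em$sws)]
  expect_gt(length(sws), 0)
  expect_lt(max(abs(sws - 2) / 2), 0.02)
  # Young's modulus closure is exact wherever speed is defined
  expect_equal(em$E, 3 * em$sws^2, tolerance = 1e-12)
  expect_true(all(em$quality[is.finite(em$sws)] >= 0.6))
})

test_that("reversed propagation and noise-floor pairs are missing", {
  pl <- constant_speed_plane(c_mps = 2)
  # reverse the lateral axis: delays now decrease outward
  pl$particle_velocity <- pl$particle_velocity[, dim(pl$particle_velocity)[2]:1, ]
  em <- sws_crosscorr(pl)
  expect_true(all(is.na(em$sws)))
  # flat traces have zero energy and are missing too
  pl0 <- constant_speed_plane()
  pl0$particle_velocity[] <- 0
  expect_true(all(is.na(sws_crosscorr(pl0)$sws)))
})

test_that("plane stacking fills a 3D volume consistent with the phantom truth", {
  st <- small_study()
  feats <- swe_feature_volumes(st)
  g <- st$grid$shape
  expect_equal(dim(feats$sws), g)
  inside <- st$prostate_mask & is.finite(feats$sws)
  expect_gt(sum(inside), 0.5 * sum(st$prostate_mask))
  # stacked speeds approximate the simulated truth field inside the gland
  rel <- abs(feats$sws[inside] - st$truth$sws[inside]) / st$truth$sws[inside]
  expect_lt(median(rel), 0.1)
  # the stacked modulus stays consistent with 3 c^2 up to interpolation error
  rel_e <- abs(feats$E[inside] - 3 * feats$sws[inside]^2) /
    (3 * feats$sws[inside]^2)
  expect_lt(median(rel_e), 0.05)
})
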