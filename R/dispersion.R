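# Spatiotemporal contrast-dispersion estimation (4D CUDI core): per voxel,
# ordinary least squares on the convection-diffusion equation
#   dC/dt = D lap(C) - v . grad(C)
# with derivatives from physical-unit central finite differences pooled over a
# spatiotemporal window of neighbouring TICs.

#' Estimate local blood velocity and diffusion from neighbouring TICs
#'
#' Central finite differences over the TIC volume give `dC/dt`, the gradient
#' and the Laplacian of the concentration field; for every voxel an ordinary
#' least-squares fit of `dC/dt = D lap(C) - v . grad(C)` over a spatial window
#' times the wash-in interval yields the local diffusion coefficient `D`
#' (mm^2/s) and blood-velocity vector `v` (mm/s). Voxels whose (column
#' equilibrated) normal system is ill-conditioned, or whose fitted `D` is
#' negative, are marked invalid.
#'
#' @param ticvol A [tic_volume]; anisotropy is handled through
#'   `voxel_size_mm` (scalar or 3-vector).
#' @param window_vox Odd spatial window edge length (voxels, default 5).
#' @param time_window_s Length-2 vector of window start/end times (s); by
#'   default the wash-in interval of the mean masked TIC (5\% of peak up to
#'   slightly past the peak).
#' @param smoothed Optional 4D array of model-smoothed intensities (e.g. from
#'   mLDRW fits) used in place of the raw data for differentiation.
#' @param cond_limit Invalidate voxels whose normal-equation condition number
#'   estimate exceeds this value (default 1e6, applied to the regressor
#'   matrix, i.e. sqrt of the normal-matrix condition).
#' @return A `dispersion_volume`: 3D arrays `vx`, `vy`, `vz`, `v_mag`, `D`,
#'   `residual` (normalised), logical `valid`.
#' @export
estimate_convective_dispersion <- function(ticvol, window_vox = 5L,
                                           time_window_s = NULL,
                                           smoothed = NULL,
                                           cond_limit = 1e6) {
  stopifnot(inherits(ticvol, "tic_volume"))
  d <- dim(ticvol$data)[1:3]
  if (window_vox %% 2L != 1L || window_vox < 3L) stop("window_vox must be odd and >= 3")
  if (any(window_vox > d)) stop("window larger than the volume")
  hw <- (window_vox - 1L) %/% 2L
  h <- rep(ticvol$voxel_size_mm, length.out = 3)
  t <- ticvol$time_s
  dt <- t[2] - t[1]
  C <- if (is.null(smoothed)) ticvol$data else smoothed
  C[!is.finite(C)] <- 0

  explicit_window <- !is.null(time_window_s)
  if (is.null(time_window_s)) {
    mtic <- apply(matrix(C, ncol = length(t))[which(ticvol$mask), , drop = FALSE], 2, mean)
    pk <- which.max(mtic)
    start <- which(mtic >= 0.05 * mtic[pk])[1]
    if (is.na(start)) start <- 1L
    stop_i <- min(length(t), pk + max(1L, round((pk - start) * 0.5)))
    time_window_s <- c(t[start], t[stop_i])
  }
  frames <- which(t >= time_window_s[1] & t <= time_window_s[2])
  frames <- frames[frames > 1L & frames < length(t)]
  if (length(frames) < 3L) {
    if (explicit_window) stop("time window leaves fewer than 3 usable frames")
    frames <- 2:(length(t) - 1L)   # degenerate mean TIC: fall back to all frames
  }

  # accumulate the 4x4 normal-equation sums over the temporal window
  acc <- vector("list", 15L)          # 10 K entries + 4 rhs + residual energy
  for (i in seq_along(acc)) acc[[i]] <- array(0, dim = d)
  nvol <- prod(d)
  for (f in frames) {
    Cf <- array(C[seq_len(nvol) + (f - 1) * nvol], dim = d)
    Ct <- array((C[seq_len(nvol) + f * nvol] -
                   C[seq_len(nvol) + (f - 2) * nvol]) / (2 * dt), dim = d)
    gx <- (shift_array(Cf, c(-1L, 0L, 0L), 0) - shift_array(Cf, c(1L, 0L, 0L), 0)) / (2 * h[1])
    gy <- (shift_array(Cf, c(0L, -1L, 0L), 0) - shift_array(Cf, c(0L, 1L, 0L), 0)) / (2 * h[2])
    gz <- (shift_array(Cf, c(0L, 0L, -1L), 0) - shift_array(Cf, c(0L, 0L, 1L), 0)) / (2 * h[3])
    lap <- (shift_array(Cf, c(-1L, 0L, 0L), 0) + shift_array(Cf, c(1L, 0L, 0L), 0) - 2 * Cf) / h[1]^2 +
      (shift_array(Cf, c(0L, -1L, 0L), 0) + shift_array(Cf, c(0L, 1L, 0L), 0) - 2 * Cf) / h[2]^2 +
      (shift_array(Cf, c(0L, 0L, -1L), 0) + shift_array(Cf, c(0L, 0L, 1L), 0) - 2 * Cf) / h[3]^2
    # regressors: a1 = lap, a2 = -gx, a3 = -gy, a4 = -gz; target b = Ct
    r1 <- lap; r2 <- -gx; r3 <- -gy; r4 <- -gz
    acc[[1]] <- acc[[1]] + r1 * r1
    acc[[2]] <- acc[[2]] + r2 * r1
    acc[[3]] <- acc[[3]] + r3 * r1
    acc[[4]] <- acc[[4]] + r4 * r1
    acc[[5]] <- acc[[5]] + r2 * r2
    acc[[6]] <- acc[[6]] + r3 * r2
    acc[[7]] <- acc[[7]] + r4 * r2
    acc[[8]] <- acc[[8]] + r3 * r3
    acc[[9]] <- acc[[9]] + r4 * r3
    acc[[10]] <- acc[[10]] + r4 * r4
    acc[[11]] <- acc[[11]] + r1 * Ct
    acc[[12]] <- acc[[12]] + r2 * Ct
    acc[[13]] <- acc[[13]] + r3 * Ct
    acc[[14]] <- acc[[14]] + r4 * Ct
    acc[[15]] <- acc[[15]] + Ct * Ct
  }
  # pool over the spatial window
  acc <- lapply(acc, box_sum3, hw = hw)

  idx <- which(ticvol$mask)
  # column equilibration: scale regressor j by 1/sqrt(sum a_j^2)
  s1 <- sqrt(acc[[1]][idx]); s2 <- sqrt(acc[[5]][idx])
  s3 <- sqrt(acc[[8]][idx]); s4 <- sqrt(acc[[10]][idx])
  nz <- s1 > 0 & s2 > 0 & s3 > 0 & s4 > 0
  s1[!nz] <- 1; s2[!nz] <- 1; s3[!nz] <- 1; s4[!nz] <- 1
  K <- list(acc[[1]][idx] / (s1 * s1), acc[[2]][idx] / (s2 * s1),
            acc[[3]][idx] / (s3 * s1), acc[[4]][idx] / (s4 * s1),
            acc[[5]][idx] / (s2 * s2), acc[[6]][idx] / (s3 * s2),
            acc[[7]][idx] / (s4 * s2), acc[[8]][idx] / (s3 * s3),
            acc[[9]][idx] / (s4 * s3), acc[[10]][idx] / (s4 * s4))
  b <- cbind(acc[[11]][idx] / s1, acc[[12]][idx] / s2,
             acc[[13]][idx] / s3, acc[[14]][idx] / s4)
  sol <- batch_solve_sym4(K, b)
  # condition estimate of the equilibrated normal matrix from Cholesky pivots
  cond_est <- (apply(sol$pivots, 1, max) / pmax(apply(sol$pivots, 1, min), 1e-300))^2
  Dv <- sol$x[, 1] / s1
  vx <- sol$x[, 2] / s2; vy <- sol$x[, 3] / s3; vz <- sol$x[, 4] / s4
  # normalised residual: 1 - explained fraction of sum b^2
  bt_b <- acc[[15]][idx]
  explained <- rowSums(sol$x * b)
  resid <- ifelse(bt_b > 0, pmax(0, 1 - explained / bt_b), NA_real_)

  valid <- nz & sol$ok & (sqrt(cond_est) <= cond_limit) & (Dv >= 0) &
    is.finite(Dv) & is.finite(vx) & is.finite(vy) & is.finite(vz)

  out <- list()
  for (nm in c("vx", "vy", "vz", "v_mag", "D", "residual")) {
    out[[nm]] <- array(NA_real_, dim = d)
  }
  out$vx[idx] <- ifelse(valid, vx, NA_real_)
  out$vy[idx] <- ifelse(valid, vy, NA_real_)
  out$vz[idx] <- ifelse(valid, vz, NA_real_)
  out$v_mag[idx] <- ifelse(valid, sqrt(vx^2 + vy^2 + vz^2), NA_real_)
  out$D[idx] <- ifelse(valid, Dv, NA_real_)
  out$residual[idx] <- ifelse(valid, resid, NA_real_)
  v <- array(FALSE, dim = d); v[idx] <- valid
  out$valid <- v
  class(out) <- "dispersion_volume"
  out
}
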