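# Shear-wave elastography features: particle velocity via the 1-D Loupas
# autocorrelator, shear-wave speed by lateral time-of-flight cross-correlation
# with parabolic sub-sample refinement, Young's modulus E = 3 rho c^2, and
# stacking of the rotational half-plane maps into 3D feature volumes.

#' Particle velocity from a complex IQ ensemble (Loupas autocorrelator)
#'
#' Lag-one autocorrelation along slow time,
#' `v = (c_us * prf / (4 pi f_c)) * arg( sum_gate x(m, n+1) conj(x(m, n)) )`,
#' with the sum (the axial gate) taken over a moving window of `gate_samples`
#' along the first (axial) array dimension.
#'
#' @param iq Complex array, slow time on the last dimension (>= 2 frames).
#' @param prf_hz Pulse-repetition frequency (Hz).
#' @param f_c_hz Ultrasound centre frequency (Hz).
#' @param c_us_mps Speed of sound (m/s).
#' @param gate_samples Axial gate length (default 1, no gating).
#' @return Array of particle velocities (m/s) with `nt - 1` slow-time frames
#'   and attribute `aliasing`: logical array, TRUE where the inter-frame phase
#'   magnitude exceeds 0.9 pi (velocity near the Nyquist limit).
#' @export
loupas_velocity <- function(iq, prf_hz, f_c_hz = 6e6, c_us_mps = 1540,
                            gate_samples = 1L) {
  dims <- dim(iq)
  if (is.null(dims)) dims <- length(iq)
  nt <- dims[length(dims)]
  if (nt < 2L) stop("IQ ensemble needs at least 2 slow-time frames")
  m <- matrix(iq, ncol = nt)
  ac <- m[, -1L, drop = FALSE] * Conj(m[, -nt, drop = FALSE])
  if (gate_samples > 1L) {
    na <- dims[1]
    nrest <- nrow(ac) / na
    acg <- ac
    hw <- (gate_samples - 1L) %/% 2L
    cs <- apply(rbind(0 + 0i, matrix(ac, nrow = na)), 2, cumsum)
    lo <- pmax(seq_len(na) - hw - 1L, 0L)
    hi <- pmin(seq_len(na) + hw, na)
    acg <- matrix(cs[hi + 1L, , drop = FALSE] - cs[lo + 1L, , drop = FALSE],
                  nrow = nrow(ac))
    ac <- acg
  }
  phi <- Arg(ac)
  v <- (c_us_mps * prf_hz / (4 * pi * f_c_hz)) * phi
  out_dims <- dims; out_dims[length(dims)] <- nt - 1L
  out <- array(v, dim = out_dims)
  attr(out, "aliasing") <- array(abs(phi) > 0.9 * pi, dim = out_dims)
  if (any(attr(out, "aliasing"))) {
    warning("inter-frame phase near +/- pi: particle velocity may be aliased")
  }
  out
}

#' Shear-wave speed, elasticity and quality maps for one plane
#'
#' For every adjacent lateral pair of particle-velocity time traces, the
#' arrival-time difference is the argmax of their normalised cross-correlation
#' refined to sub-sample precision with a three-point parabola. The shear-wave
#' speed is `lateral_spacing / dt`, Young's modulus `E = 3 rho c^2` with
#' rho = 1000 kg/m^3 (reported in kPa, i.e. `E_kPa = 3 sws^2`), and the quality
#' the correlation-peak height. Pairs with non-positive delay (propagation
#' opposite the assumed outward direction), sub-floor quality or flat traces
#' are missing.
#'
#' @param plane A list with `particle_velocity` (axial x lateral x time),
#'   `lateral_spacing_mm` and `frame_interval_s` (as produced by the phantom
#'   simulator).
#' @param quality_floor Minimum correlation peak for a valid estimate
#'   (default 0.6).
#' @return An `elasticity_maps` list: matrices `sws` (m/s), `E` (kPa) and
#'   `quality` on the (axial x lateral-midpoint) grid, plus `axial_mm` and
#'   `lateral_mm` when the plane carries them.
#' @export
sws_crosscorr <- function(plane, quality_floor = 0.6) {
  pv <- plane$particle_velocity
  stopifnot(length(dim(pv)) == 3L)
  na <- dim(pv)[1]; nl <- dim(pv)[2]; nt <- dim(pv)[3]
  if (nl < 2L) stop("need at least 2 lateral positions")
  dt_s <- plane$frame_interval_s
  dx_mm <- plane$lateral_spacing_mm

  # all (axial, lateral-pair) trace pairs cross-correlated at once via FFT
  nf <- 2L^ceiling(log2(2L * nt))
  A <- matrix(aperm(pv, c(3, 1, 2)), nrow = nt)   # columns: (axial, lateral)
  Ap <- rbind(A, matrix(0, nf - nt, ncol(A)))
  FA <- stats::mvfft(Ap)
  i1 <- as.vector(outer(seq_len(na), (seq_len(nl - 1L) - 1L) * na, `+`))
  i2 <- i1 + na
  CC <- Re(stats::mvfft(Conj(FA[, i1, drop = FALSE]) * FA[, i2, drop = FALSE],
                        inverse = TRUE)) / nf
  en <- colSums(A^2)
  norm <- sqrt(en[i1] * en[i2])

  # peak over lags 0..nt-1 (negative lags wrap to the top rows and are the
  # reversed-propagation case: excluded by contract)
  CCpos <- CC[seq_len(nt), , drop = FALSE]
  pk <- max.col(t(CCpos), ties.method = "first")
  npair <- length(pk)
  pkval <- CCpos[cbind(pk, seq_len(npair))]
  quality <- ifelse(norm > 0, pkval / norm, 0)
  quality <- pmin(pmax(quality, 0), 1)

  # parabolic sub-sample refinement around the peak (wrapped neighbours)
  lm1 <- ifelse(pk - 1L >= 1L, pk - 1L, nf)
  lp1 <- pk + 1L
  ym1 <- CC[cbind(lm1, seq_len(npair))]
  yp1 <- CC[cbind(lp1, seq_len(npair))]
  den <- ym1 - 2 * pkval + yp1
  frac <- ifelse(abs(den) > 0, 0.5 * (ym1 - yp1) / den, 0)
  frac <- pmin(pmax(frac, -0.5), 0.5)
  lag <- (pk - 1L) + frac
  delay_s <- lag * dt_s

  valid <- norm > 0 & quality >= quality_floor & delay_s > 0
  sws <- ifelse(valid, (dx_mm / 1000) / delay_s, NA_real_)
  sws_m <- matrix(sws, nrow = na)
  out <- list(
    sws = sws_m,
    E = 3 * sws_m^2,                 # kPa: 3 * rho * c^2 with rho = 1000
    quality = matrix(quality, nrow = na),
    pose_rad = plane$pose_rad,
    axial_mm = plane$axial_mm
  )
  if (!is.null(plane$lateral_radius_mm)) {
    r <- plane$lateral_radius_mm
    out$lateral_mm <- (r[-length(r)] + r[-1]) / 2
  }
  class(out) <- "elasticity_maps"
  out
}

#' @keywords internal
bilinear_na <- function(M, ax, lat, xq, rq) {
  # NA-aware bilinear interpolation of matrix M (rows ~ ax, cols ~ lat) at the
  # query points (xq, rq); NA corners drop out with weight renormalisation
  n <- length(xq)
  fi <- findInterval(xq, ax, rightmost.closed = TRUE)
  fj <- findInterval(rq, lat, rightmost.closed = TRUE)
  ok <- fi >= 1L & fi < length(ax) & fj >= 1L & fj < length(lat)
  out <- rep(NA_real_, n)
  ii <- which(ok)
  if (!length(ii)) return(out)
  i0 <- fi[ii]; j0 <- fj[ii]
  tx <- (xq[ii] - ax[i0]) / (ax[i0 + 1L] - ax[i0])
  ty <- (rq[ii] - lat[j0]) / (lat[j0 + 1L] - lat[j0])
  tx <- pmin(pmax(tx, 0), 1); ty <- pmin(pmax(ty, 0), 1)
  w00 <- (1 - tx) * (1 - ty); w10 <- tx * (1 - ty)
  w01 <- (1 - tx) * ty;       w11 <- tx * ty
  v00 <- M[cbind(i0, j0)];         v10 <- M[cbind(i0 + 1L, j0)]
  v01 <- M[cbind(i0, j0 + 1L)];    v11 <- M[cbind(i0 + 1L, j0 + 1L)]
  W <- cbind(w00, w10, w01, w11)
  V <- cbind(v00, v10, v01, v11)
  W[is.na(V)] <- 0
  V[is.na(V)] <- 0
  ws <- rowSums(W)
  out[ii] <- ifelse(ws > 0, rowSums(W * V) / ws, NA_real_)
  out
}

#' Stack rotational-plane elasticity maps into a 3D volume
#'
#' Every voxel is expressed in cylindrical coordinates about the probe axis
#' (axial position x, radius r, rotation angle theta) and its value linearly
#' interpolated between the two planes nearest in rotation angle, each sampled
#' bilinearly in (x, r). Missing map pixels drop out with weight
#' renormalisation; voxels outside the angular or radial coverage are missing.
#'
#' @param maps List of `elasticity_maps` (one per plane, with `pose_rad`).
#' @param grid_shape,voxel_size_mm,centre_mm Target grid (as in the phantom).
#' @param fields Character vector of map fields to stack.
#' @return Named list of 3D arrays.
#' @export
stack_planes <- function(maps, grid_shape, voxel_size_mm, centre_mm,
                         fields = c("sws", "E", "quality")) {
  stopifnot(length(maps) >= 2L)
  poses <- vapply(maps, function(m) m$pose_rad, 1)
  o <- order(poses)
  maps <- maps[o]; poses <- poses[o]
  ax <- maps[[1]]$axial_mm
  lat <- maps[[1]]$lateral_mm
  if (is.null(ax) || is.null(lat)) stop("plane maps need axial_mm/lateral_mm")

  d <- grid_shape
  co <- coord_arrays(d, voxel_size_mm, centre_mm)
  r <- sqrt(co$y^2 + co$z^2)
  th <- atan2(co$z, co$y)
  # angular coverage of the half-plane fan: each pose owns its angular bin
  dth <- if (length(poses) > 1L) stats::median(diff(poses)) else pi
  covered <- th > min(poses) - dth / 2 - 1e-12 & th < max(poses) + dth / 2 + 1e-12
  fi <- findInterval(th, poses)
  k0 <- pmin(pmax(fi, 1L), length(poses) - 1L)
  k1 <- k0 + 1L
  wt <- (th - poses[k0]) / (poses[k1] - poses[k0])
  wt <- pmin(pmax(wt, 0), 1)

  out <- list()
  for (f in fields) {
    vol <- array(NA_real_, dim = d)
    idx <- which(covered)
    if (length(idx)) {
      v <- rep(NA_real_, length(idx))
      for (k in unique(k0[idx])) {
        sel <- idx[k0[idx] == k]
        v0 <- bilinear_na(maps[[k]][[f]], ax, lat, co$x[sel], r[sel])
        v1 <- bilinear_na(maps[[k + 1L]][[f]], ax, lat, co$x[sel], r[sel])
        w1 <- wt[sel]; w0 <- 1 - w1
        w0[is.na(v0)] <- 0; w1[is.na(v1)] <- 0
        v0[is.na(v0)] <- 0; v1[is.na(v1)] <- 0
        ws <- w0 + w1
        v[match(sel, idx)] <- ifelse(ws > 0, (w0 * v0 + w1 * v1) / ws, NA_real_)
      }
      vol[idx] <- v
    }
    out[[f]] <- vol
  }
  out
}

#' Elasticity feature volumes for a phantom study
#'
#' Runs [sws_crosscorr] on every acquired plane and [stack_planes] onto the
#' study grid.
#'
#' @param study A `phantom_study` with `swe_planes`.
#' @param quality_floor Passed to [sws_crosscorr].
#' @return List of 3D arrays `sws` (m/s), `E` (kPa), `quality`.
#' @export
swe_feature_volumes <- function(study, quality_floor = 0.6) {
  stopifnot(inherits(study, "phantom_study"), !is.null(study$swe_planes))
  maps <- lapply(study$swe_planes$planes, sws_crosscorr,
                 quality_floor = quality_floor)
  stack_planes(maps, study$grid$shape, study$grid$voxel_size_mm,
               study$grid$centre_mm)
}
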