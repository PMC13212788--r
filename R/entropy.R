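# Velocity-entropy features: blood-velocity vectors estimated from contrast
# arrival-time delays (local plane fit of the arrival-time map gives the
# slowness vector), followed by Shannon entropy and conditional entropy of the
# quantized velocity-direction field over a local window. Disordered
# microvasculature produces a high-entropy direction field.

#' Contrast arrival-time map
#'
#' The arrival time tau is the earliest time the TIC reaches
#' `threshold_fraction` of its peak. When per-voxel mLDRW fits are supplied
#' the fitted (noise-free) curve is thresholded by bisection on its rising
#' edge; otherwise the first crossing of the raw TIC is located by linear
#' interpolation.
#'
#' @param x An `mldrw_fit_volume` (preferred) or a [tic_volume].
#' @param threshold_fraction Fraction of the peak in (0, 1), default 0.5.
#' @return 3D array of arrival times (s); missing where no crossing exists.
#' @export
arrival_time_map <- function(x, threshold_fraction = 0.5) {
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    stop("threshold_fraction must be in (0, 1)")
  }
  if (inherits(x, "mldrw_fit_volume")) {
    d <- dim(x$kappa)
    out <- array(NA_real_, dim = d)
    idx <- which(x$converged & is.finite(x$kappa))
    if (length(idx)) {
      kap <- x$kappa[idx]; mu <- x$mu[idx]; t0 <- x$t0[idx]
      s_peak <- (sqrt(1 + 4 * kap^2 * mu^2) - 1) / (2 * kap)
      out[idx] <- t0 + rising_crossing(kap, mu, s_peak, threshold_fraction)
    }
    return(out)
  }
  stopifnot(inherits(x, "tic_volume"))
  d <- dim(x$data)[1:3]
  t <- x$time_s
  idx <- which(x$mask)
  Y <- matrix(x$data, ncol = length(t))[idx, , drop = FALSE]
  pk <- apply(Y, 1, max)
  thr <- threshold_fraction * pk
  out <- array(NA_real_, dim = d)
  cross <- Y >= thr
  first <- max.col(cross, ties.method = "first")
  has <- cross[cbind(seq_len(nrow(Y)), first)] & pk > 0
  tau <- rep(NA_real_, nrow(Y))
  f1 <- first[has]
  y1 <- Y[cbind(which(has), f1)]
  prev <- pmax(f1 - 1L, 1L)
  y0 <- Y[cbind(which(has), prev)]
  frac <- ifelse(f1 > 1 & y1 > y0, (thr[has] - y0) / (y1 - y0), 0)
  frac <- pmin(pmax(frac, 0), 1)
  tau[has] <- t[prev] + frac * (t[f1] - t[prev])
  out[idx] <- tau
  out
}

#' Blood-velocity field from arrival-time delays
#'
#' A local least-squares plane fit of the arrival-time map over a cubic window
#' gives the slowness vector (the arrival-time gradient, s/mm). The velocity
#' points opposite the gradient (flow runs toward later arrival), with
#' magnitude `1 / |grad tau|`. Voxels whose gradient magnitude falls below the
#' resolution floor (arbitrarily fast apparent flow) or whose window holds
#' fewer than half its voxels are invalid.
#'
#' @param tau 3D arrival-time array (s), NA where undefined.
#' @param window_vox Odd window edge length (voxels), default 5.
#' @param voxel_size_mm Voxel spacing (mm).
#' @param slowness_floor_s_per_mm Minimum resolvable gradient magnitude.
#' @return A `velocity_field`: arrays `sx, sy, sz` (slowness), `dx, dy, dz`
#'   (unit direction), `v_mag` (mm/s) and logical `valid`.
#' @export
velocity_field_from_delays <- function(tau, window_vox = 5L, voxel_size_mm = 1,
                                       slowness_floor_s_per_mm = 1e-3) {
  d <- dim(tau)
  stopifnot(length(d) == 3L, window_vox %% 2L == 1L, window_vox >= 3L)
  hw <- (window_vox - 1L) %/% 2L
  h <- voxel_size_mm
  ok <- is.finite(tau)
  tz <- ifelse(ok, tau, 0)
  okn <- ok * 1

  co <- coord_arrays(d, h, c(0, 0, 0))
  # window sums for the plane fit tau ~ a + b dx + c dy + e dz, coordinates
  # taken relative to the window centre via absolute coords (equivalent fit)
  S <- list(
    n    = box_sum3(okn, hw),
    x    = box_sum3(okn * co$x, hw),
    y    = box_sum3(okn * co$y, hw),
    z    = box_sum3(okn * co$z, hw),
    xx   = box_sum3(okn * co$x^2, hw),
    xy   = box_sum3(okn * co$x * co$y, hw),
    xz   = box_sum3(okn * co$x * co$z, hw),
    yy   = box_sum3(okn * co$y^2, hw),
    yz   = box_sum3(okn * co$y * co$z, hw),
    zz   = box_sum3(okn * co$z^2, hw),
    t    = box_sum3(tz, hw),
    xt   = box_sum3(tz * co$x, hw),
    yt   = box_sum3(tz * co$y, hw),
    zt   = box_sum3(tz * co$z, hw)
  )
  idx <- which(ok & S$n >= (window_vox^3) / 2)
  K <- list(S$n[idx], S$x[idx], S$y[idx], S$z[idx],
            S$xx[idx], S$xy[idx], S$xz[idx],
            S$yy[idx], S$yz[idx], S$zz[idx])
  b <- cbind(S$t[idx], S$xt[idx], S$yt[idx], S$zt[idx])
  sol <- batch_solve_sym4(K, b)
  g <- sol$x[, 2:4, drop = FALSE]
  gn <- sqrt(rowSums(g^2))
  # snap numerically-zero components so exactly axis-aligned flow does not
  # oscillate across direction-bin boundaries
  g[abs(g) < 1e-9 * gn] <- 0
  gn <- sqrt(rowSums(g^2))
  valid <- sol$ok & is.finite(gn) & gn >= slowness_floor_s_per_mm

  out <- list()
  for (nm in c("sx", "sy", "sz", "dx", "dy", "dz", "v_mag")) {
    out[[nm]] <- array(NA_real_, dim = d)
  }
  out$sx[idx] <- ifelse(valid, g[, 1], NA_real_)
  out$sy[idx] <- ifelse(valid, g[, 2], NA_real_)
  out$sz[idx] <- ifelse(valid, g[, 3], NA_real_)
  out$dx[idx] <- ifelse(valid, -g[, 1] / gn, NA_real_)
  out$dy[idx] <- ifelse(valid, -g[, 2] / gn, NA_real_)
  out$dz[idx] <- ifelse(valid, -g[, 3] / gn, NA_real_)
  out$v_mag[idx] <- ifelse(valid, 1 / gn, NA_real_)
  v <- array(FALSE, dim = d)
  v[idx] <- valid
  out$valid <- v
  class(out) <- "velocity_field"
  out
}

#' @keywords internal
direction_bins <- function(field, azimuth_bins, elevation_bins) {
  az <- atan2(field$dy, field$dx)               # [-pi, pi)
  el <- asin(pmin(pmax(field$dz, -1), 1))       # [-pi/2, pi/2]
  az_bin <- pmin(floor((az + pi) / (2 * pi) * azimuth_bins) + 1, azimuth_bins)
  el_bin <- pmin(floor((el + pi / 2) / pi * elevation_bins) + 1, elevation_bins)
  bin <- (el_bin - 1) * azimuth_bins + az_bin
  bin[!field$valid] <- NA_real_
  bin
}

#' Entropy and conditional entropy of the velocity-direction field
#'
#' Velocity directions are quantized into `azimuth_bins x elevation_bins`
#' solid-angle bins. Over a cubic window around each voxel, the ordered
#' face-adjacent valid pairs are pooled; the map `H` is the Shannon entropy of
#' the pair centre-member direction histogram and `H_cond` the conditional
#' entropy of a voxel's direction given its face neighbour's, both in bits.
#' Using the same pair population for both guarantees `H_cond <= H`
#' everywhere. Windows with fewer than `min_valid` valid voxels are missing.
#'
#' @param field A `velocity_field` from [velocity_field_from_delays].
#' @param window_vox Odd window edge length, default 7.
#' @param azimuth_bins,elevation_bins Direction quantization (default 8 x 4).
#' @param min_valid Minimum valid voxels per window (default 8).
#' @return An `entropy_maps` list: 3D arrays `H` and `H_cond` (bits).
#' @export
velocity_entropy_maps <- function(field, window_vox = 7L, azimuth_bins = 8L,
                                  elevation_bins = 4L, min_valid = 8L) {
  stopifnot(inherits(field, "velocity_field"),
            window_vox %% 2L == 1L, azimuth_bins * elevation_bins >= 2L)
  d <- dim(field$valid)
  hw <- (window_vox - 1L) %/% 2L
  nb <- azimuth_bins * elevation_bins
  bin <- direction_bins(field, azimuth_bins, elevation_bins)

  H <- array(NA_real_, dim = d)
  H_cond <- array(NA_real_, dim = d)
  centres <- which(!is.na(bin))
  valid_n <- box_sum3(ifelse(is.na(bin), 0, 1), hw)
  centres <- centres[valid_n[centres] >= min_valid]
  if (!length(centres)) {
    return(structure(list(H = H, H_cond = H_cond, n_bins = nb),
                     class = "entropy_maps"))
  }

  # pad by the window half-width so every window gathers without clipping
  dp <- d + 2L * hw
  bin_p <- array(NA_integer_, dim = dp)
  bin_p[hw + seq_len(d[1]), hw + seq_len(d[2]), hw + seq_len(d[3])] <-
    as.integer(bin)

  # joint bin of (voxel, face neighbour at +1 along axis a), stored at the
  # voxel; NA when either end is invalid
  joints <- vector("list", 3L)
  for (a in 1:3) {
    off <- c(0L, 0L, 0L); off[a] <- -1L
    nbin <- shift_array(bin_p, off, fill = NA_integer_)
    joints[[a]] <- (bin_p - 1L) * nb + nbin
  }

  ijk <- arrayInd(centres, d)
  centres_p <- as.integer(vox_linear_index(sweep(ijk, 2, hw, `+`), dp))
  og <- as.matrix(expand.grid(i = -hw:hw, j = -hw:hw, k = -hw:hw))
  delta <- as.integer(og[, 3] * dp[1] * dp[2] + og[, 2] * dp[1] + og[, 1])
  n_c <- length(centres)
  nb2 <- nb * nb
  lin <- outer(delta, centres_p, `+`)
  row0 <- rep(seq_len(n_c) - 1L, each = nrow(og))
  # tabulate silently ignores the NA keys of invalid pairs
  jk <- vector("list", 3L); ck <- vector("list", 3L); nk <- vector("list", 3L)
  for (a in 1:3) {
    jj <- joints[[a]][lin]
    bc <- (jj - 1L) %/% nb + 1L
    jk[[a]] <- row0 * nb2 + jj
    ck[[a]] <- row0 * nb + bc
    nk[[a]] <- row0 * nb + (jj - (bc - 1L) * nb)
  }
  tabj <- tabulate(unlist(jk, use.names = FALSE), nbins = n_c * nb2)
  tabc <- tabulate(unlist(ck, use.names = FALSE), nbins = n_c * nb)
  tabn <- tabulate(unlist(nk, use.names = FALSE), nbins = n_c * nb)
  tot <- colSums(matrix(tabc, nrow = nb))
  if (!any(tot > 0)) {
    return(structure(list(H = H, H_cond = H_cond, n_bins = nb),
                     class = "entropy_maps"))
  }

  # plug-in entropies from tabulated per-window histograms; computed on
  # probabilities so a single occupied bin yields exactly -1 * log2(1) = 0
  marg_entropy <- function(M) {
    P <- matrix(M, nrow = nb) / rep(pmax(tot, 1L), each = nb)
    s <- colSums(-P * log2(pmax(P, 1e-300)))
    s[s == 0] <- 0                          # normalize any IEEE -0
    ifelse(tot > 0, s, NA_real_)
  }
  Hc <- marg_entropy(tabc)
  Hn <- marg_entropy(tabn)
  # the joint histogram is sparse: group its nonzero counts, which come out
  # sorted by window
  nz <- which(tabj > 0L)
  row <- (nz - 1L) %/% nb2 + 1L
  p <- tabj[nz] / tot[row]
  cs <- cumsum(-p * log2(p))
  last <- c(which(row[-1L] != row[-length(row)]), length(row))
  Hj <- rep(NA_real_, n_c)
  hjv <- diff(c(0, cs[last]))
  hjv[hjv == 0] <- 0
  Hj[row[last]] <- hjv

  has <- tot > 0
  hv <- ifelse(has, Hc, NA_real_)
  hcv <- ifelse(has, pmin(pmax(Hj - Hn, 0), hv), NA_real_)
  H[centres] <- hv
  H_cond[centres] <- hcv
  structure(list(H = H, H_cond = H_cond, n_bins = nb), class = "entropy_maps")
}
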