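# Synthetic-study generator. Emulates every input the real pipeline consumes:
# prostate/zone/lesion geometry, mLDRW-shaped CEUS loops with lesion-dependent
# hemodynamics, an analytic convecting-diffusing bolus, propagating shear-wave
# planes with region-dependent speed, sparse histology slices and clinical
# scalars — all with recorded ground truth.

#' Phantom configuration
#'
#' Defines the study conditions of a synthetic patient. Defaults give a ~36 cc
#' ellipsoidal prostate on a 32^3 grid of 2 mm voxels, with csPCa lesions
#' occupying ~5\% of the prostate (the dataset prevalence prior), benign and
#' malignant hemodynamic/stiffness ranges that are separated but overlapping,
#' and a 1 Hz, 90 s CEUS loop.
#'
#' @param grid_shape Integer 3-vector of voxels per axis (x = probe axis,
#'   y = lateral, z = anteroposterior, anterior positive).
#' @param voxel_size_mm Isotropic voxel spacing (mm).
#' @param n_lesions Number of csPCa lesions.
#' @param lesion_radius_mm_range Admissible range for the mean lesion radius.
#' @param target_prevalence Target fraction of prostate voxels that are
#'   malignant; must lie in (0, 1).
#' @param lesion_zone Zone constraint for lesion centres: `"any"`, `"pz"` or
#'   `"tz"`.
#' @param hemodynamics_benign,hemodynamics_malignant Lists of mLDRW parameter
#'   ranges, each with 2-vectors `kappa` (1/s), `mu` (s), `t0` (s), `auc`
#'   (a.u.).
#' @param stiffness_benign,stiffness_malignant Shear-wave speed ranges (m/s).
#' @param noise_sigma CEUS additive-noise scale, as a fraction of each voxel's
#'   peak intensity.
#' @param param_smooth_benign,param_smooth_malignant Gaussian smoothing sigma
#'   (voxels) of the within-class parameter fields; the larger malignant value
#'   makes lesion TICs more spatially correlated (more coherent
#'   microvasculature patch).
#' @param frame_interval_s,duration_s CEUS temporal sampling.
#' @param n_planes Number of shear-wave elastography planes (rotational sweep).
#' @param swe_prf_hz SWE slow-time sampling rate of the particle-velocity
#'   movies (Hz).
#' @param swe_pulse_sigma_s Temporal width (Gaussian sigma, s) of the shear
#'   pulse.
#' @param swe_background_mps Shear-wave speed outside the prostate (m/s).
#' @param prostate_centre_mm World position of the prostate centre; the probe
#'   is at the origin with its axis along x.
#' @param histology_spacing_mm Histology slice spacing (mm), 4 by default.
#' @param psa_density_benign,psa_density_cspca Log-mean PSA density (ng/mL/cc)
#'   for patients without/with csPCa.
#' @param seed Integer seed; identical configs generate bit-identical studies.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(grid_shape = c(32L, 32L, 32L),
                           voxel_size_mm = 2,
                           n_lesions = 2L,
                           lesion_radius_mm_range = c(3, 14),
                           target_prevalence = 0.05,
                           lesion_zone = c("any", "pz", "tz"),
                           hemodynamics_benign = list(
                             kappa = c(0.4, 1.0), mu = c(25, 40),
                             t0 = c(8, 12), auc = c(60, 120)),
                           hemodynamics_malignant = list(
                             kappa = c(1.2, 2.5), mu = c(12, 22),
                             t0 = c(5, 9), auc = c(100, 200)),
                           stiffness_benign = c(1.5, 2.5),
                           stiffness_malignant = c(3.0, 4.5),
                           noise_sigma = 0.05,
                           param_smooth_benign = 0.75,
                           param_smooth_malignant = 2.0,
                           frame_interval_s = 1,
                           duration_s = 90,
                           n_planes = 25L,
                           swe_prf_hz = 2000,
                           swe_pulse_sigma_s = 0.0015,
                           swe_background_mps = 1.5,
                           prostate_centre_mm = c(0, 0, 35),
                           histology_spacing_mm = 4,
                           psa_density_benign = 0.12,
                           psa_density_cspca = 0.22,
                           seed = 1L) {
  lesion_zone <- match.arg(lesion_zone)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8L),
            voxel_size_mm > 0, n_lesions >= 0L,
            target_prevalence > 0, target_prevalence < 1,
            all(lesion_radius_mm_range > 0),
            diff(lesion_radius_mm_range) >= 0,
            noise_sigma >= 0, frame_interval_s > 0,
            duration_s > frame_interval_s, n_planes >= 2L)
  for (h in list(hemodynamics_benign, hemodynamics_malignant)) {
    stopifnot(all(c("kappa", "mu", "t0", "auc") %in% names(h)),
              all(vapply(h, length, 1L) == 2L),
              h$kappa[1] > 0, h$mu[1] > 0, h$t0[1] >= 0, h$auc[1] > 0)
  }
  stopifnot(all(stiffness_benign > 0), all(stiffness_malignant > 0))
  cfg <- as.list(environment())
  cfg$grid_shape <- as.integer(grid_shape)
  class(cfg) <- "phantom_config"
  cfg
}

#' A separable benchmark phantom configuration
#'
#' Same geometry as [phantom_config] but with benign and malignant parameter
#' ranges pulled apart (no overlap in `kappa`, `mu` and shear-wave speed).
#' Used as the benchmark condition under which the trained classifier is
#' expected to reach a high AUC.
#'
#' @param ... Overrides passed to [phantom_config].
#' @return A `phantom_config`.
#' @export
phantom_config_separable <- function(...) {
  phantom_config(
    hemodynamics_benign = list(kappa = c(0.4, 0.8), mu = c(28, 40),
                               t0 = c(8, 12), auc = c(60, 110)),
    hemodynamics_malignant = list(kappa = c(1.6, 2.8), mu = c(12, 20),
                                  t0 = c(5, 8), auc = c(130, 220)),
    stiffness_benign = c(1.4, 2.2),
    stiffness_malignant = c(3.2, 4.6),
    ...
  )
}

#' Generate prostate, zone and lesion geometry
#'
#' Builds an ellipsoidal prostate split into an inner transition zone (TZ,
#' shifted anteriorly) and a peripheral-zone (PZ) shell, then places
#' ellipsoidal lesions whose joint volume matches the target prevalence.
#' Fails explicitly (rather than silently clipping) when the requested
#' prevalence is unreachable with the configured lesion radii.
#'
#' @param config A [phantom_config].
#' @return A `phantom_study` containing masks, grid info and clinical scalars;
#'   imaging data are added by the `simulate_*` generators.
#' @export
generate_geometry <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  d <- config$grid_shape
  h <- config$voxel_size_mm
  co <- coord_arrays(d, h, config$prostate_centre_mm)
  ctr <- config$prostate_centre_mm
  semi <- c(0.75, 0.64, 0.56) * d * h / 2   # prostate semi-axes (mm)
  q <- ((co$x - ctr[1]) / semi[1])^2 + ((co$y - ctr[2]) / semi[2])^2 +
    ((co$z - ctr[3]) / semi[3])^2
  prostate <- q <= 1
  if (sum(prostate) < 50) stop("grid too small to contain a prostate")
  # TZ: inner ellipsoid, shifted anteriorly (away from the probe)
  tz_semi <- 0.62 * semi
  tz_ctr <- ctr + c(0, 0, 0.18 * semi[3])
  qtz <- ((co$x - tz_ctr[1]) / tz_semi[1])^2 + ((co$y - tz_ctr[2]) / tz_semi[2])^2 +
    ((co$z - tz_ctr[3]) / tz_semi[3])^2
  tz <- prostate & (qtz <= 1)
  pz <- prostate & !tz

  lesion <- array(FALSE, dim = d)
  truth_lesion_id <- array(0L, dim = d)
  if (config$n_lesions > 0L) {
    res <- with_seed(derive_seed(config$seed, "geometry"), {
      place_lesions(config, prostate, pz, tz, co, semi, ctr)
    })
    lesion <- res$lesion
    truth_lesion_id <- res$lesion_id
    prev <- sum(lesion) / sum(prostate)
    rel <- abs(prev - config$target_prevalence) / config$target_prevalence
    if (rel > 0.2) {
      stop(sprintf(
        "geometry could not meet target prevalence: achieved %.4f vs target %.4f (relative error %.0f%%); adjust lesion radii or count",
        prev, config$target_prevalence, 100 * rel))
    }
  }

  volume_cc <- sum(prostate) * h^3 / 1000
  has_cspca <- any(lesion)
  clinical <- with_seed(derive_seed(config$seed, "clinical"), {
    psad <- exp(rnorm(1, log(if (has_cspca) config$psa_density_cspca else
      config$psa_density_benign), 0.25))
    list(psa_ng_ml = psad * volume_cc, volume_cc = volume_cc, psa_density = psad)
  })

  structure(list(
    config = config,
    prostate_mask = prostate, pz_mask = pz, tz_mask = tz,
    lesion_mask = lesion, lesion_id = truth_lesion_id,
    clinical = clinical,
    grid = list(shape = d, voxel_size_mm = h, centre_mm = ctr),
    truth = list()
  ), class = "phantom_study")
}

#' @keywords internal
place_lesions <- function(config, prostate, pz, tz, co, semi, ctr) {
  d <- config$grid_shape; h <- config$voxel_size_mm
  n <- config$n_lesions
  target_vox <- config$target_prevalence * sum(prostate)
  # split target volume across lesions with random (but bounded) proportions
  prop <- runif(n, 0.6, 1.4)
  prop <- prop / sum(prop)
  vol_mm3 <- target_vox * h^3 * prop
  radii <- (3 * vol_mm3 / (4 * pi))^(1 / 3)
  rng <- config$lesion_radius_mm_range
  if (any(radii < rng[1] - 1e-9) || any(radii > rng[2] + 1e-9)) {
    stop(sprintf(
      "infeasible prevalence/lesion-size combination: required mean radii %s mm outside allowed [%g, %g] mm",
      paste(sprintf("%.1f", radii), collapse = ", "), rng[1], rng[2]))
  }
  zone_mask <- switch(config$lesion_zone, any = prostate, pz = pz, tz = tz)
  inside <- which(zone_mask)
  lesion <- array(FALSE, dim = d)
  lesion_id <- array(0L, dim = d)
  for (i in seq_len(n)) {
    ratios <- runif(3, 0.75, 1.3)
    ax <- radii[i] * ratios / prod(ratios)^(1 / 3)
    placed <- FALSE
    for (attempt in 1:300) {
      c_idx <- sample(inside, 1)
      cx <- co$x[c_idx]; cy <- co$y[c_idx]; cz <- co$z[c_idx]
      # lesion must fit inside the prostate: check scaled centre distance
      margin <- max(ax)
      qc <- ((cx - ctr[1]) / (semi[1] - margin))^2 +
        ((cy - ctr[2]) / (semi[2] - margin))^2 +
        ((cz - ctr[3]) / (semi[3] - margin))^2
      if (any(semi - margin <= 0) || qc > 1) next
      ql <- ((co$x - cx) / ax[1])^2 + ((co$y - cy) / ax[2])^2 + ((co$z - cz) / ax[3])^2
      cand <- ql <= 1
      if (!any(cand)) next
      if (any(cand & lesion)) next   # keep lesions disjoint
      lesion <- lesion | cand
      lesion_id[cand] <- i
      placed <- TRUE
      break
    }
    if (!placed) stop("could not place a lesion inside the prostate; relax geometry")
  }
  list(lesion = lesion & prostate, lesion_id = lesion_id)
}

# Smooth within-class random field mapped to a uniform range. The pointwise
# marginal is ~Uniform(lo, hi); `sigma_vox` sets the spatial correlation.
#' @keywords internal
smooth_uniform_field <- function(d, range, sigma_vox) {
  g <- array(rnorm(prod(d)), dim = d)
  if (sigma_vox > 0) {
    g <- gaussian_smooth3(g, sigma_vox)
    g <- (g - mean(g)) / stats::sd(as.vector(g))
  }
  range[1] + (range[2] - range[1]) * stats::pnorm(g)
}

#' Simulate the CEUS loop of a phantom study
#'
#' Every voxel's TIC is the mLDRW forward model evaluated with that voxel's
#' true parameters (drawn from the benign or malignant ranges as smooth
#' within-class fields) plus additive Gaussian noise scaled by the voxel's
#' peak intensity. TICs are generated inside the prostate plus a 3-voxel
#' margin so neighbourhood-based estimators have full support.
#'
#' @param study A `phantom_study` with geometry.
#' @param config Optional config override (defaults to `study$config`).
#' @return The study with `$ceus_loop` (a [tic_volume]) and
#'   `$truth$kappa/mu/t0/auc` parameter maps added.
#' @export
simulate_ceus_loop <- function(study, config = study$config) {
  stopifnot(inherits(study, "phantom_study"))
  d <- config$grid_shape
  t <- seq(0, config$duration_s, by = config$frame_interval_s)
  mask <- dilate_mask(study$prostate_mask, 3L)
  les <- study$lesion_mask

  fields <- with_seed(derive_seed(config$seed, "ceus"), {
    fb <- lapply(config$hemodynamics_benign, smooth_uniform_field,
                 d = d, sigma_vox = config$param_smooth_benign)
    fm <- lapply(config$hemodynamics_malignant, smooth_uniform_field,
                 d = d, sigma_vox = config$param_smooth_malignant)
    noise <- array(rnorm(prod(d) * length(t)), dim = c(d, length(t)))
    list(fb = fb, fm = fm, noise = noise)
  })
  truth <- fields$fb
  for (p in names(truth)) truth[[p]][les] <- fields$fm[[p]][les]

  if (config$duration_s < max(truth$mu[mask] + truth$t0[mask])) {
    warning("loop duration shorter than mu + t0 of some voxels: wash-out truncated")
  }

  idx <- which(mask)
  theta <- cbind(truth$kappa[idx], truth$mu[idx], truth$t0[idx], truth$auc[idx])
  Yc <- mldrw_eval(theta, t)$f
  data <- array(0, dim = c(d, length(t)))
  nvol <- prod(d)
  if (config$noise_sigma > 0) {
    pk <- apply(Yc, 1, max)
    noise_m <- matrix(fields$noise, ncol = length(t))[idx, , drop = FALSE]
    Yc <- Yc + noise_m * (config$noise_sigma * pk)
  }
  for (j in seq_along(t)) data[idx + (j - 1) * nvol] <- Yc[, j]

  for (p in names(truth)) truth[[p]][!mask] <- NA_real_
  study$ceus_loop <- tic_volume(data, t, mask = mask,
                                voxel_size_mm = config$voxel_size_mm)
  study$truth$kappa <- truth$kappa
  study$truth$mu <- truth$mu
  study$truth$t0 <- truth$t0
  study$truth$auc <- truth$auc
  study
}

#' Analytic convecting-diffusing bolus field
#'
#' Samples the closed-form solution of the 3D convection-diffusion equation
#' for a point release,
#' \deqn{C(x,t) = A\,(4\pi D (t + t_{ref}))^{-3/2}
#'   \exp\{-\|x - x_0 - v t\|^2 / (4 D (t + t_{ref}))\},}
#' on a regular grid. Serves as the exact oracle for the convective-dispersion
#' estimator.
#'
#' @param grid_shape Voxels per axis.
#' @param voxel_size_mm Voxel spacing (mm).
#' @param v Blood-velocity 3-vector (mm/s).
#' @param D Diffusion coefficient (mm^2/s); must be positive.
#' @param times Sample times (s).
#' @param t_ref Reference (release-to-first-frame) time offset (s) controlling
#'   the initial bolus width.
#' @param x0 Release point (mm) relative to the grid centre.
#' @param peak_scale Value of the spatial peak at the first sampled time.
#' @return A list with `ticvol` (a [tic_volume]) and `truth = list(v, D)`.
#' @export
simulate_dispersion_field <- function(grid_shape = c(21L, 21L, 21L),
                                      voxel_size_mm = 1,
                                      v = c(0, 0, 0), D = 1,
                                      times = seq(0, 4, by = 0.25),
                                      t_ref = 4, x0 = c(0, 0, 0),
                                      peak_scale = 1) {
  if (D <= 0) stop("D must be positive")
  stopifnot(length(v) == 3L, t_ref > 0)
  d <- as.integer(grid_shape)
  co <- coord_arrays(d, voxel_size_mm, c(0, 0, 0))
  nt <- length(times)
  data <- array(0, dim = c(d, nt))
  nvol <- prod(d)
  amp0 <- (4 * pi * D * (times[1] + t_ref))^(-3 / 2)
  A <- peak_scale / amp0
  for (j in seq_len(nt)) {
    tt <- times[j]
    s2 <- 4 * D * (tt + t_ref)
    r2 <- (co$x - x0[1] - v[1] * tt)^2 + (co$y - x0[2] - v[2] * tt)^2 +
      (co$z - x0[3] - v[3] * tt)^2
    data[seq_len(nvol) + (j - 1) * nvol] <- A * (pi * s2)^(-3 / 2) * exp(-r2 / s2)
  }
  mask <- array(TRUE, dim = d)
  list(ticvol = tic_volume(data, times, mask = mask, voxel_size_mm = voxel_size_mm),
       truth = list(v = v, D = D))
}

#' Simulate rotational shear-wave elastography planes
#'
#' The probe sweeps `n_planes` half-planes about its axis (the x-axis), each
#' sampled on an (axial, lateral-radius) pixel grid. In each plane a shear
#' pulse propagates along the lateral axis away from the probe with the local
#' true shear-wave speed; the arrival time accumulates
#' `spacing / c_local` between adjacent positions, so time-of-flight
#' estimation recovers the local speed. The truth shear-wave-speed volume is
#' stored in `$truth$sws`.
#'
#' @param study A `phantom_study` with geometry.
#' @param config Optional config override.
#' @return The study with `$swe_planes`: a list with per-plane
#'   `particle_velocity` arrays (axial x lateral x time), plane poses (rad),
#'   lateral radii (mm) and timing metadata.
#' @export
simulate_swe_planes <- function(study, config = study$config) {
  stopifnot(inherits(study, "phantom_study"))
  d <- config$grid_shape; h <- config$voxel_size_mm
  ctr <- config$prostate_centre_mm
  sws <- with_seed(derive_seed(config$seed, "swe"), {
    f <- smooth_uniform_field(d, config$stiffness_benign, config$param_smooth_benign)
    fm <- smooth_uniform_field(d, config$stiffness_malignant, config$param_smooth_malignant)
    f[study$lesion_mask] <- fm[study$lesion_mask]
    f[!study$prostate_mask] <- config$swe_background_mps
    f
  })
  study$truth$sws <- sws

  ax <- grid_coordinates(d, h, ctr)
  r_max <- sqrt(max(abs(ax$y))^2 + max(ax$z)^2)
  r <- seq(h, r_max, by = h)
  poses <- (seq_len(config$n_planes) - 0.5) * pi / config$n_planes
  dt <- 1 / config$swe_prf_hz
  # frame span: slowest transit plus pulse support
  t_total <- sum(h / (min(sws) * 1000)) * length(r) + 8 * config$swe_pulse_sigma_s
  times <- seq(0, t_total, by = dt)
  pulse_sigma <- config$swe_pulse_sigma_s
  if (1 / (2 * pi * pulse_sigma) > config$swe_prf_hz / 2) {
    stop("shear pulse bandwidth exceeds the Nyquist rate of the plane movies (aliasing)")
  }

  planes <- vector("list", config$n_planes)
  for (k in seq_len(config$n_planes)) {
    th <- poses[k]
    # sample local speed at plane pixels (nearest voxel)
    yk <- outer(rep(1, length(ax$x)), r * cos(th))
    zk <- outer(rep(1, length(ax$x)), r * sin(th))
    xk <- outer(ax$x, rep(1, length(r)))
    ii <- pmin(pmax(round((xk - ax$x[1]) / h) + 1, 1), d[1])
    jj <- pmin(pmax(round((yk - ax$y[1]) / h) + 1, 1), d[2])
    kk0 <- round((zk - ax$z[1]) / h) + 1
    inside_z <- kk0 >= 1 & kk0 <= d[3]
    kk <- pmin(pmax(kk0, 1), d[3])
    c_loc <- matrix(sws[cbind(as.vector(ii), as.vector(jj), as.vector(kk))],
                    nrow = length(ax$x))
    c_loc[!inside_z] <- config$swe_background_mps
    # cumulative arrival time along the lateral axis (s); speed in m/s = mm/ms
    t_arr <- t(apply(h / (c_loc * 1000), 1, cumsum))
    pv <- array(0, dim = c(length(ax$x), length(r), length(times)))
    for (j in seq_along(r)) {
      pv[, j, ] <- exp(-outer(t_arr[, j], times, function(a, b) (b - a)^2) /
                         (2 * pulse_sigma^2))
    }
    planes[[k]] <- list(particle_velocity = pv, pose_rad = th,
                        lateral_radius_mm = r, axial_mm = ax$x,
                        lateral_spacing_mm = h, frame_interval_s = dt,
                        true_sws = c_loc)
  }
  study$swe_planes <- list(planes = planes, poses = poses,
                           lateral_radius_mm = r, axial_mm = ax$x,
                           frame_interval_s = dt)
  study
}

#' Synthesize a complex IQ ensemble encoding a particle-velocity movie
#'
#' Encodes particle velocity as the slow-time inter-frame phase progression
#' `phi[n+1] - phi[n] = 4 pi f_c v / (c_us PRF)`, the relation the Loupas
#' autocorrelator inverts.
#'
#' @param particle_velocity Array with slow time as last dimension (m/s).
#' @param prf_hz Slow-time sampling rate (Hz).
#' @param f_c_hz Ultrasound centre frequency (Hz).
#' @param c_us_mps Speed of sound (m/s).
#' @param amplitude Constant echo amplitude.
#' @return Complex array of the same shape.
#' @export
synthesize_iq <- function(particle_velocity, prf_hz, f_c_hz = 6e6,
                          c_us_mps = 1540, amplitude = 1) {
  dims <- dim(particle_velocity)
  nt <- dims[length(dims)]
  m <- matrix(particle_velocity, ncol = nt)
  dphi <- 4 * pi * f_c_hz * m / (c_us_mps * prf_hz)
  phi <- cbind(0, t(apply(dphi[, -nt, drop = FALSE], 1, cumsum)))
  if (nt == 1) phi <- matrix(0, nrow(m), 1)
  iq <- amplitude * exp(1i * phi)
  array(iq, dim = dims)
}

#' Sample sparse histology slices from the lesion mask
#'
#' Extracts binary lesion masks on transverse planes (orthogonal to the probe
#' axis) every `spacing_mm`, emulating the 4 mm-thick whole-mount sectioning
#' of radical-prostatectomy specimens.
#'
#' @param study A `phantom_study` with geometry.
#' @param spacing_mm Slice spacing (mm, default 4); must be at least one voxel.
#' @return A `histology_slices` list: `slice_index` (x indices),
#'   `slice_x_mm`, binary `labels` and prostate cross-sections `prostate`.
#' @export
slice_histology <- function(study, spacing_mm = study$config$histology_spacing_mm) {
  stopifnot(inherits(study, "phantom_study"))
  h <- study$grid$voxel_size_mm
  if (spacing_mm < h - 1e-9) stop("slice spacing smaller than the voxel size")
  step <- max(1L, round(spacing_mm / h))
  pro_x <- which(apply(study$prostate_mask, 1, any))
  if (!length(pro_x)) stop("no prostate voxels to slice")
  sl <- as.integer(seq(min(pro_x), max(pro_x), by = step))
  ax <- grid_coordinates(study$grid$shape, h, study$grid$centre_mm)
  structure(list(
    slice_index = sl,
    slice_x_mm = ax$x[sl],
    spacing_mm = step * h,
    pixel_spacing_mm = h,
    labels = lapply(sl, function(i) study$lesion_mask[i, , ]),
    prostate = lapply(sl, function(i) study$prostate_mask[i, , ])
  ), class = "histology_slices")
}

#' Generate a complete phantom study
#'
#' Convenience wrapper running [generate_geometry], [simulate_ceus_loop],
#' [simulate_swe_planes] and [slice_histology].
#'
#' @param config A [phantom_config].
#' @return A fully populated `phantom_study`.
#' @export
generate_phantom_study <- function(config = phantom_config()) {
  study <- generate_geometry(config)
  study <- simulate_ceus_loop(study)
  study <- simulate_swe_planes(study)
  study$histology_slices <- slice_histology(study)
  study
}

#' @export
print.phantom_study <- function(x, ...) {
  cat(sprintf("phantom_study: grid %s, prostate %d voxels (%.1f cc), %d lesion voxels (prevalence %.3f)\n",
              paste(x$grid$shape, collapse = "x"), sum(x$prostate_mask),
              x$clinical$volume_cc, sum(x$lesion_mask),
              sum(x$lesion_mask) / sum(x$prostate_mask)))
  cat(sprintf("  components: %s\n",
              paste(intersect(c("ceus_loop", "swe_planes", "histology_slices"),
                              names(x)), collapse = ", ")))
  invisible(x)
}
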