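# Feature-extraction orchestration: runs every feature module on one study
# and assembles the per-voxel feature volumes, location channels and clinical
# scalars consumed by the classifier.

#' Location channels on the study grid
#'
#' `loc_pz`: peripheral-zone indicator; `loc_dist`: Euclidean distance (mm)
#' from the probe origin; `loc_elev`: elevation angle (rad) of the voxel's
#' position vector out of the probe's transverse plane.
#'
#' @param study A `phantom_study` (or any list with `grid`, `pz_mask`).
#' @return Named list of 3D arrays.
#' @export
location_channels <- function(study) {
  co <- coord_arrays(study$grid$shape, study$grid$voxel_size_mm,
                     study$grid$centre_mm)
  r <- sqrt(co$x^2 + co$y^2 + co$z^2)
  list(loc_pz = study$pz_mask * 1,
       loc_dist = r,
       loc_elev = atan2(co$x, sqrt(co$y^2 + co$z^2)))
}

#' Extract all classifier features for one study
#'
#' Runs the temporal mLDRW fits, convective-dispersion estimation, spatial
#' TIC-similarity maps, velocity-entropy maps and SWE elasticity maps, and
#' bundles them with location channels, clinical scalars, the reference
#' standard and the anatomy masks.
#'
#' @param study A complete `phantom_study`.
#' @param reference Optional precomputed `reference_volume` (built with
#'   [build_reference] otherwise).
#' @param similarity_ring_mm Ring radius for the similarity maps.
#' @param entropy_window_vox Window for the velocity-entropy maps.
#' @param verbose Print stage timings.
#' @return A `patient_features` object: `features` (named 3D arrays),
#'   `location`, `clinical` (named scalars), `reference`, masks, `grid`.
#' @export
extract_features <- function(study, reference = NULL, similarity_ring_mm = 2,
                             entropy_window_vox = 7L, verbose = FALSE) {
  stopifnot(inherits(study, "phantom_study"), !is.null(study$ceus_loop))
  tick <- function(label, expr) {
    t0 <- Sys.time()
    r <- expr
    if (verbose) message(sprintf("  %-12s %.2f s", label,
                                 as.numeric(Sys.time() - t0, units = "secs")))
    r
  }
  tv <- study$ceus_loop
  fits <- tick("mldrw", fit_mldrw_volume(tv, max_iter = 25L, tol = 1e-4))
  tf <- tick("temporal", derive_temporal_features(fits))
  disp <- tick("dispersion", estimate_convective_dispersion(tv))
  sim <- tick("similarity", similarity_maps(tv, ring_radius_mm = similarity_ring_mm))
  em <- tick("entropy", {
    tau <- arrival_time_map(fits)
    vf <- velocity_field_from_delays(tau, voxel_size_mm = tv$voxel_size_mm)
    velocity_entropy_maps(vf, window_vox = entropy_window_vox)
  })
  swe <- tick("swe", swe_feature_volumes(study))
  if (is.null(reference)) reference <- tick("reference", build_reference(study))

  features <- list(
    kappa = fits$kappa, mu = fits$mu, t0 = fits$t0,
    peak = tf$peak, wash_in = tf$wash_in,
    cd_vmag = disp$v_mag, cd_d = disp$D,
    sa_corr = sim$corr_time, sa_coh = sim$coh_freq, sa_mi = sim$mi,
    ve_h = em$H, ve_hcond = em$H_cond,
    swe_sws = swe$sws, swe_e = swe$E, swe_quality = swe$quality)
  clinical <- c(volume_cc = study$clinical$volume_cc,
                psa_density = study$clinical$psa_ng_ml /
                  study$clinical$volume_cc)
  structure(list(features = features, location = location_channels(study),
                 clinical = clinical, reference = reference,
                 prostate_mask = study$prostate_mask, pz_mask = study$pz_mask,
                 tz_mask = study$tz_mask, grid = study$grid,
                 patient_id = study$config$seed),
            class = "patient_features")
}

#' Per-feature standardisation statistics over a patient scope
#'
#' Mean and standard deviation of every feature, location channel and
#' clinical scalar over the prostate voxels of the scope patients. The two
#' scopes reflect the leakage trade-off: `entire_dataset` pools all patients,
#' `train_folds_only` is leakage-safe.
#'
#' @param patients List of `patient_features`.
#' @param scope_ids Indices of patients entering the statistics.
#' @param stats_scope Label stored in the record.
#' @return A `feature_stats` data.frame (feature, mean, sd, constant flag)
#'   with the scope recorded as an attribute.
#' @export
compute_feature_stats <- function(patients, scope_ids = seq_along(patients),
                                  stats_scope = "train_folds_only") {
  nms <- c(names(patients[[1]]$features), names(patients[[1]]$location),
           names(patients[[1]]$clinical))
  pooled <- lapply(nms, function(nm) {
    unlist(lapply(patients[scope_ids], function(p) {
      v <- if (nm %in% names(p$features)) p$features[[nm]] else
        if (nm %in% names(p$location)) p$location[[nm]] else p$clinical[[nm]]
      if (length(v) == 1L) v else v[p$prostate_mask]
    }), use.names = FALSE)
  })
  m <- vapply(pooled, function(v) mean(v, na.rm = TRUE), 1)
  s <- vapply(pooled, function(v) stats::sd(v, na.rm = TRUE), 1)
  m[!is.finite(m)] <- 0
  constant <- !is.finite(s) | s < 1e-12
  s[constant] <- 1
  out <- data.frame(feature = nms, mean = m, sd = s, constant = constant,
                    stringsAsFactors = FALSE)
  attr(out, "stats_scope") <- stats_scope
  structure(out, class = c("feature_stats", "data.frame"))
}

#' @keywords internal
standardize_value <- function(v, stats, nm) {
  row <- match(nm, stats$feature)
  if (is.na(row)) stop(sprintf("no persisted statistics for feature '%s'", nm))
  z <- (v - stats$mean[row]) / stats$sd[row]
  z[!is.finite(z)] <- 0     # missing values impute to the post-z mean
  z
}

#' Standardised per-branch channel stack for one patient
#'
#' Builds the (n_voxels x channels) input matrix of a branch: the branch's
#' feature volumes followed by the location channels, z-scored with the
#' persisted statistics and missing values imputed to 0.
#'
#' @param patient A `patient_features`.
#' @param branch_features,location Channel names.
#' @param stats A `feature_stats` record.
#' @return Matrix (prod(grid shape) x n_channels).
#' @export
branch_stack <- function(patient, branch_features, location, stats) {
  nms <- c(branch_features, location)
  out <- matrix(0, prod(patient$grid$shape), length(nms))
  for (j in seq_along(nms)) {
    nm <- nms[j]
    v <- if (nm %in% names(patient$features)) patient$features[[nm]] else
      patient$location[[nm]]
    out[, j] <- standardize_value(as.vector(v), stats, nm)
  }
  out
}

#' @keywords internal
clinical_row <- function(patient, clinical, stats) {
  vapply(clinical, function(nm)
    standardize_value(patient$clinical[[nm]], stats, nm), 1)
}
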