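# Standard-format persistence: NIfTI for 3D/4D volumes, YAML for configs and
# metadata, CSV/JSON for tables, and an md5 provenance manifest.

#' Write a 3D or 4D array as NIfTI
#'
#' @param x Numeric or logical array (logical is stored as 0/1).
#' @param path Output path (`.nii.gz`).
#' @param voxel_size_mm Isotropic voxel edge (mm); 4D arrays additionally
#'   take `time_step_s` for the 4th dimension.
#' @param time_step_s Frame interval for 4D data (seconds).
#' @return The path, invisibly.
#' @export
save_volume <- function(x, path, voxel_size_mm = 1, time_step_s = 1) {
  if (is.logical(x)) x <- x * 1
  nd <- length(dim(x))
  stopifnot(nd %in% c(2L, 3L, 4L))
  pd <- c(rep(voxel_size_mm, min(nd, 3L)), if (nd == 4L) time_step_s)
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path Input path.
#' @return Array with attribute `pixdim`.
#' @export
load_volume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim = dim(img))
  attr(out, "pixdim") <- RNifti::pixdim(img)
  out
}

#' @keywords internal
save_yaml <- function(x, path) {
  # full double precision so numeric metadata round-trips losslessly
  writeLines(yaml::as.yaml(x, precision = 15L), path)
  invisible(path)
}

#' @keywords internal
load_yaml <- function(path) yaml::read_yaml(path)

#' Persist a phantom study to a directory
#'
#' Masks and truth maps go to one NIfTI file each, the CEUS loop to a 4D
#' NIfTI with a YAML time-axis sidecar, SWE plane movies to per-plane 3D
#' NIfTI stacks with a shared geometry sidecar, histology slices to a NIfTI
#' stack with slice positions in YAML, and the configuration and clinical
#' scalars to YAML.
#'
#' @param study A `phantom_study`.
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
save_study <- function(study, dir) {
  stopifnot(inherits(study, "phantom_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  h <- study$grid$voxel_size_mm
  fp <- function(...) file.path(dir, paste0(...))
  for (nm in c("prostate_mask", "pz_mask", "tz_mask", "lesion_mask",
               "lesion_id")) {
    save_volume(study[[nm]], fp(nm, ".nii.gz"), h)
  }
  for (nm in names(study$truth)) {
    save_volume(study$truth[[nm]], fp("truth_", nm, ".nii.gz"), h)
  }
  tv <- study$ceus_loop
  save_volume(tv$data, fp("ceus.nii.gz"), h, diff(tv$time_s[1:2]))
  save_volume(tv$mask, fp("ceus_mask.nii.gz"), h)
  save_yaml(list(time_s = tv$time_s, voxel_size_mm = tv$voxel_size_mm),
            fp("ceus_meta.yaml"))
  sw <- study$swe_planes
  for (k in seq_along(sw$planes)) {
    save_volume(sw$planes[[k]]$particle_velocity,
                fp(sprintf("swe_plane_%02d.nii.gz", k)), h)
    save_volume(sw$planes[[k]]$true_sws,
                fp(sprintf("swe_true_sws_%02d.nii.gz", k)), h)
  }
  save_yaml(list(n_planes = length(sw$planes), poses = sw$poses,
                 lateral_radius_mm = sw$lateral_radius_mm,
                 axial_mm = sw$axial_mm,
                 frame_interval_s = sw$frame_interval_s,
                 lateral_spacing_mm = sw$planes[[1]]$lateral_spacing_mm),
            fp("swe_meta.yaml"))
  hs <- study$histology_slices
  save_volume(simplify2array(hs$labels), fp("histology_labels.nii.gz"),
              hs$pixel_spacing_mm)
  save_volume(simplify2array(hs$prostate), fp("histology_prostate.nii.gz"),
              hs$pixel_spacing_mm)
  save_yaml(list(slice_index = hs$slice_index, slice_x_mm = hs$slice_x_mm,
                 spacing_mm = hs$spacing_mm,
                 pixel_spacing_mm = hs$pixel_spacing_mm),
            fp("histology_meta.yaml"))
  save_yaml(list(clinical = study$clinical, grid = study$grid,
                 config = unclass(study$config)), fp("study.yaml"))
  invisible(dir)
}

#' Load a phantom study persisted by [save_study]
#'
#' @param dir Study directory.
#' @return A `phantom_study`.
#' @export
load_study <- function(dir) {
  fp <- function(...) file.path(dir, paste0(...))
  meta <- load_yaml(fp("study.yaml"))
  cfg <- meta$config
  for (nm in c("grid_shape", "n_lesions", "n_planes")) {
    if (!is.null(cfg[[nm]])) cfg[[nm]] <- as.integer(cfg[[nm]])
  }
  class(cfg) <- "phantom_config"
  grid <- meta$grid
  grid$shape <- as.integer(unlist(grid$shape))
  study <- list(config = cfg, grid = grid, clinical = meta$clinical)
  for (nm in c("prostate_mask", "pz_mask", "tz_mask", "lesion_mask")) {
    study[[nm]] <- array(load_volume(fp(nm, ".nii.gz")) > 0.5, grid$shape)
  }
  study$lesion_id <- array(load_volume(fp("lesion_id.nii.gz")), grid$shape)
  study$truth <- list()
  for (f in list.files(dir, pattern = "^truth_.*\\.nii\\.gz$")) {
    nm <- sub("^truth_(.*)\\.nii\\.gz$", "\\1", f)
    study$truth[[nm]] <- load_volume(file.path(dir, f))
  }
  cm <- load_yaml(fp("ceus_meta.yaml"))
  study$ceus_loop <- tic_volume(
    load_volume(fp("ceus.nii.gz")),
    time_s = as.numeric(unlist(cm$time_s)),
    mask = array(load_volume(fp("ceus_mask.nii.gz")) > 0.5, grid$shape),
    voxel_size_mm = cm$voxel_size_mm)
  sm <- load_yaml(fp("swe_meta.yaml"))
  planes <- lapply(seq_len(sm$n_planes), function(k) {
    list(particle_velocity = load_volume(
           fp(sprintf("swe_plane_%02d.nii.gz", k))),
         pose_rad = as.numeric(unlist(sm$poses))[k],
         lateral_radius_mm = as.numeric(unlist(sm$lateral_radius_mm)),
         axial_mm = as.numeric(unlist(sm$axial_mm)),
         lateral_spacing_mm = sm$lateral_spacing_mm,
         frame_interval_s = sm$frame_interval_s,
         true_sws = load_volume(fp(sprintf("swe_true_sws_%02d.nii.gz", k))))
  })
  study$swe_planes <- list(planes = planes,
                           poses = as.numeric(unlist(sm$poses)),
                           lateral_radius_mm =
                             as.numeric(unlist(sm$lateral_radius_mm)),
                           axial_mm = as.numeric(unlist(sm$axial_mm)),
                           frame_interval_s = sm$frame_interval_s)
  hm <- load_yaml(fp("histology_meta.yaml"))
  lab <- load_volume(fp("histology_labels.nii.gz"))
  pro <- load_volume(fp("histology_prostate.nii.gz"))
  n_sl <- dim(lab)[3]
  study$histology_slices <- structure(list(
    slice_index = as.integer(unlist(hm$slice_index)),
    slice_x_mm = as.numeric(unlist(hm$slice_x_mm)),
    spacing_mm = hm$spacing_mm, pixel_spacing_mm = hm$pixel_spacing_mm,
    labels = lapply(seq_len(n_sl), function(i) lab[, , i] > 0.5),
    prostate = lapply(seq_len(n_sl), function(i) pro[, , i] > 0.5)),
    class = "histology_slices")
  class(study) <- "phantom_study"
  study
}

#' Persist extracted features and reference volumes
#'
#' One NIfTI per feature map plus a JSON index of names/units, the location
#' channels, the reference probability/label/weight volumes and the clinical
#' scalars.
#'
#' @param pf A `patient_features`.
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
save_patient_features <- function(pf, dir) {
  stopifnot(inherits(pf, "patient_features"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  h <- pf$grid$voxel_size_mm
  fp <- function(...) file.path(dir, paste0(...))
  units <- c(kappa = "1/s", mu = "s", t0 = "s", peak = "a.u.",
             wash_in = "a.u./s", cd_vmag = "mm/s", cd_d = "mm^2/s",
             sa_corr = "unitless", sa_coh = "unitless", sa_mi = "bits",
             ve_h = "bits", ve_hcond = "bits", swe_sws = "m/s",
             swe_e = "kPa", swe_quality = "unitless")
  for (nm in names(pf$features)) {
    save_volume(pf$features[[nm]], fp("feature_", nm, ".nii.gz"), h)
  }
  jsonlite::write_json(
    list(features = names(pf$features),
         units = as.list(units[names(pf$features)])),
    fp("features_index.json"), auto_unbox = TRUE, pretty = TRUE)
  for (nm in names(pf$location)) {
    save_volume(pf$location[[nm]], fp(nm, ".nii.gz"), h)
  }
  save_volume(pf$reference$p, fp("reference_p.nii.gz"), h)
  save_volume(pf$reference$label, fp("reference_label.nii.gz"), h)
  save_volume(pf$reference$weight, fp("reference_weight.nii.gz"), h)
  for (nm in c("prostate_mask", "pz_mask", "tz_mask")) {
    save_volume(pf[[nm]], fp(nm, ".nii.gz"), h)
  }
  save_yaml(list(clinical = as.list(pf$clinical), grid = pf$grid,
                 patient_id = pf$patient_id), fp("patient.yaml"))
  invisible(dir)
}

#' Load features persisted by [save_patient_features]
#'
#' @param dir Feature directory.
#' @return A `patient_features`.
#' @export
load_patient_features <- function(dir) {
  fp <- function(...) file.path(dir, paste0(...))
  meta <- load_yaml(fp("patient.yaml"))
  grid <- meta$grid
  grid$shape <- as.integer(unlist(grid$shape))
  idx <- jsonlite::read_json(fp("features_index.json"), simplifyVector = TRUE)
  features <- lapply(idx$features, function(nm)
    array(load_volume(fp("feature_", nm, ".nii.gz")), grid$shape))
  names(features) <- idx$features
  location <- lapply(c("loc_pz", "loc_dist", "loc_elev"), function(nm)
    array(load_volume(fp(nm, ".nii.gz")), grid$shape))
  names(location) <- c("loc_pz", "loc_dist", "loc_elev")
  reference <- structure(list(
    p = array(load_volume(fp("reference_p.nii.gz")), grid$shape),
    label = array(load_volume(fp("reference_label.nii.gz")), grid$shape),
    weight = array(load_volume(fp("reference_weight.nii.gz")), grid$shape)),
    class = "reference_volume")
  masks <- lapply(c("prostate_mask", "pz_mask", "tz_mask"), function(nm)
    array(load_volume(fp(nm, ".nii.gz")) > 0.5, grid$shape))
  structure(list(features = features, location = location,
                 clinical = unlist(meta$clinical), reference = reference,
                 prostate_mask = masks[[1]], pz_mask = masks[[2]],
                 tz_mask = masks[[3]], grid = grid,
                 patient_id = meta$patient_id),
            class = "patient_features")
}

#' Write a provenance manifest for a run directory
#'
#' Records the package version, the seed, an md5 hash of the configuration
#' and the md5 checksum of every artifact (the manifest itself and log files
#' excluded), so byte-identical reruns yield identical manifests.
#'
#' @param dir Run directory.
#' @param config The pipeline configuration (echoed and hashed).
#' @param seed Global seed.
#' @return The manifest list, invisibly; written to `manifest.json`.
#' @export
write_manifest <- function(dir, config, seed) {
  files <- list.files(dir, recursive = TRUE)
  files <- setdiff(files, c("manifest.json",
                            grep("\\.log$|\\.jsonl$", files, value = TRUE)))
  sums <- tools::md5sum(file.path(dir, files))
  names(sums) <- files
  manifest <- list(
    package_version = as.character(utils::packageVersion("mpuscad")),
    seed = seed,
    config_md5 = digest::digest(config, algo = "md5"),
    checksums = as.list(sums))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
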