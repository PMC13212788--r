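# Pipeline orchestration: phantom generation -> reference -> features ->
# training -> evaluation, with stage toggles, on-disk artifacts in standard
# formats and a provenance manifest. A single global seed fans out to every
# stage through derive_seed(seed, tag).

#' Pipeline configuration
#'
#' @param out_dir Run directory for artifacts.
#' @param n_patients Number of synthetic patients.
#' @param grid_shape Voxel grid per patient.
#' @param separable Use the class-separable phantom configuration.
#' @param phantom_overrides Named list of [phantom_config] arguments applied
#'   on top of the chosen base configuration.
#' @param branches Branch definition passed to [architecture_spec] (NULL =
#'   default three branches). Dropping a group (e.g. no `swe`) trains on the
#'   remaining groups.
#' @param n_folds,n_repeats Cross-validation layout.
#' @param train A [train_config].
#' @param stats_scope Standardization scope (see [run_crossval]).
#' @param with_control Also train the location-only control classifier.
#' @param stages Stages to execute, in dependency order.
#' @param seed Global seed.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, n_patients = 8L,
                            grid_shape = c(24L, 24L, 24L), separable = TRUE,
                            phantom_overrides = list(), branches = NULL,
                            n_folds = 4L, n_repeats = 1L,
                            train = train_config(), stats_scope = "train_folds_only",
                            with_control = TRUE,
                            stages = c("phantom", "reference", "features",
                                       "train", "evaluate"),
                            seed = 1L) {
  stages <- match.arg(stages, c("phantom", "reference", "features", "train",
                                "evaluate"), several.ok = TRUE)
  structure(as.list(environment()), class = "pipeline_config")
}

#' @keywords internal
patient_dirs <- function(config) {
  file.path(config$out_dir,
            sprintf("patient_%03d", seq_len(config$n_patients)))
}

#' @keywords internal
make_patient_config <- function(config, i) {
  base <- if (config$separable) phantom_config_separable else phantom_config
  args <- c(list(grid_shape = config$grid_shape,
                 seed = derive_seed(config$seed, paste0("patient_", i))),
            config$phantom_overrides)
  do.call(base, args)
}

#' Run the pipeline
#'
#' Executes the requested stages in dependency order. Each stage reads its
#' inputs from the run directory (so any stage can be rerun from persisted
#' upstream artifacts) and writes its outputs there; a provenance manifest
#' with per-file checksums is written last.
#'
#' @param config A [pipeline_config].
#' @param verbose Print stage progress.
#' @return Invisibly, a list with the evaluation tables (when the stages ran)
#'   and the manifest.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  dirs <- patient_dirs(config)
  say <- function(...) if (verbose) message(sprintf(...))
  need <- function(path, stage) {
    if (!file.exists(path)) {
      stop(sprintf("stage '%s': missing upstream artifact '%s'", stage, path))
    }
    path
  }

  if ("phantom" %in% config$stages) {
    say("stage phantom: %d patients", config$n_patients)
    for (i in seq_len(config$n_patients)) {
      save_study(generate_phantom_study(make_patient_config(config, i)),
                 dirs[i])
    }
  }

  if ("reference" %in% config$stages) {
    say("stage reference")
    for (i in seq_len(config$n_patients)) {
      need(file.path(dirs[i], "study.yaml"), "reference")
      study <- load_study(dirs[i])
      ref <- build_reference(study)
      h <- study$grid$voxel_size_mm
      save_volume(ref$p, file.path(dirs[i], "reference_p.nii.gz"), h)
      save_volume(ref$label, file.path(dirs[i], "reference_label.nii.gz"), h)
      save_volume(ref$weight, file.path(dirs[i], "reference_weight.nii.gz"),
                  h)
    }
  }

  if ("features" %in% config$stages) {
    say("stage features")
    for (i in seq_len(config$n_patients)) {
      need(file.path(dirs[i], "study.yaml"), "features")
      study <- load_study(dirs[i])
      g <- study$grid$shape
      rp <- need(file.path(dirs[i], "reference_p.nii.gz"), "features")
      ref <- structure(list(
        p = array(load_volume(rp), g),
        label = array(load_volume(
          file.path(dirs[i], "reference_label.nii.gz")), g),
        weight = array(load_volume(
          file.path(dirs[i], "reference_weight.nii.gz")), g)),
        class = "reference_volume")
      pf <- suppressWarnings(extract_features(study, reference = ref))
      save_patient_features(pf, file.path(dirs[i], "features"))
    }
  }

  result <- list()
  if (any(c("train", "evaluate") %in% config$stages)) {
    patients <- lapply(seq_len(config$n_patients), function(i) {
      need(file.path(dirs[i], "features", "patient.yaml"), "train")
      load_patient_features(file.path(dirs[i], "features"))
    })
    spec <- if (is.null(config$branches)) architecture_spec() else
      architecture_spec(branches = config$branches,
                        expected_param_range = NULL)
  }

  if ("train" %in% config$stages) {
    say("stage train: full model")
    cv <- run_crossval(patients, spec, config$train, config$n_folds,
                       config$n_repeats, config$stats_scope,
                       seed = derive_seed(config$seed, "train_full"),
                       verbose = verbose)
    result$cv_full <- cv
    utils::write.csv(cv$fold_aucs,
                     file.path(config$out_dir, "fold_aucs_full.csv"),
                     row.names = FALSE)
    log_lines <- apply(cv$fold_aucs, 1, function(r)
      jsonlite::toJSON(as.list(r), auto_unbox = TRUE))
    writeLines(unlist(log_lines),
               file.path(config$out_dir, "training_log.jsonl"))
    if (config$with_control) {
      say("stage train: control model")
      cvc <- run_crossval(patients, control_location_spec(), config$train,
                          config$n_folds, config$n_repeats,
                          config$stats_scope,
                          seed = derive_seed(config$seed, "train_control"),
                          verbose = verbose)
      result$cv_control <- cvc
      utils::write.csv(cvc$fold_aucs,
                       file.path(config$out_dir, "fold_aucs_control.csv"),
                       row.names = FALSE)
    }
    saveRDS(result[grep("^cv_", names(result))],
            file.path(config$out_dir, "crossval.rds"))
  }

  if ("evaluate" %in% config$stages) {
    say("stage evaluate")
    if (is.null(result$cv_full)) {
      cvp <- need(file.path(config$out_dir, "crossval.rds"), "evaluate")
      stored <- readRDS(cvp)
      result$cv_full <- stored$cv_full
      result$cv_control <- stored$cv_control
    }
    tabs <- list(full = crossval_zone_table(result$cv_full))
    if (!is.null(result$cv_control)) {
      tabs$control <- crossval_zone_table(result$cv_control)
    }
    res <- do.call(rbind, lapply(names(tabs), function(nm)
      cbind(model = nm, tabs[[nm]])))
    utils::write.csv(res, file.path(config$out_dir, "results.csv"),
                     row.names = FALSE)
    jsonlite::write_json(res, file.path(config$out_dir, "results.json"),
                         dataframe = "rows", auto_unbox = TRUE, pretty = TRUE)
    result$results <- res
  }

  result$manifest <- write_manifest(config$out_dir, unclass(config),
                                    config$seed)
  invisible(result)
}

#' Benchmark-scale training configuration
#'
#' Pool caps and the epoch schedule sized so a 40-patient, 7-fold x 2-repeat
#' experiment (plus the control model) fits a 15-minute single-CPU budget.
#'
#' @param ... Overrides forwarded to [train_config].
#' @return A `train_config`.
#' @export
benchmark_train_config <- function(...) {
  args <- list(batch_size = 128L, max_epochs = 12L, patience = 4L,
               pretrain_pos_cap = 400L, finetune_cap = 3000L,
               val_cap = 2400L, pretrain_val_cap = 400L)
  over <- list(...)
  args[names(over)] <- over
  do.call(train_config, args)
}

#' End-to-end phantom experiment (in memory)
#'
#' Generates a cohort of synthetic patients, extracts all features, runs
#' repeated stratified cross-validation for the full model and for the
#' location-only control, and (optionally) re-runs one fold to verify
#' bit-for-bit determinism under the fixed seed.
#'
#' @param n_patients Cohort size.
#' @param grid_shape Voxel grid per patient.
#' @param separable Use the class-separable phantom configuration.
#' @param n_folds,n_repeats Cross-validation layout.
#' @param config A [train_config]; defaults to [benchmark_train_config].
#' @param seed Global seed.
#' @param check_determinism Re-run repeat 1 / fold 1 of the full model and
#'   compare predictions bitwise.
#' @param verbose Print progress.
#' @return List: `full`, `control` (each a `crossval_result`), `auc_full`,
#'   `auc_control` (mean over repeat x fold), `deterministic`, `timings_s`.
#' @export
run_phantom_experiment <- function(n_patients = 40L,
                                   grid_shape = c(32L, 32L, 32L),
                                   separable = TRUE, n_folds = 7L,
                                   n_repeats = 2L,
                                   config = benchmark_train_config(),
                                   seed = 1L, check_determinism = TRUE,
                                   verbose = FALSE) {
  timings <- c()
  clock <- function(label, expr) {
    t0 <- Sys.time()
    r <- force(expr)
    timings[label] <<- as.numeric(Sys.time() - t0, units = "secs")
    if (verbose) message(sprintf("%s: %.1f s", label, timings[label]))
    r
  }
  base <- if (separable) phantom_config_separable else phantom_config
  patients <- clock("features", lapply(seq_len(n_patients), function(i) {
    st <- generate_phantom_study(
      base(grid_shape = grid_shape,
           seed = derive_seed(seed, paste0("patient_", i))))
    suppressWarnings(extract_features(st))
  }))
  cv_full <- clock("cv_full", run_crossval(
    patients, architecture_spec(), config, n_folds, n_repeats,
    seed = derive_seed(seed, "train_full"), verbose = verbose))
  cv_control <- clock("cv_control", run_crossval(
    patients, control_location_spec(), config, n_folds, n_repeats,
    seed = derive_seed(seed, "train_control"), verbose = verbose))
  deterministic <- NA
  if (check_determinism) {
    deterministic <- clock("determinism", {
      plan <- cv_full$plan[[1]]
      fold_seed <- derive_seed(derive_seed(seed, "train_full"),
                               "rep1_fold1")
      rerun <- run_fold(patients, which(plan$fold != 1L),
                        which(plan$fold == 1L), architecture_spec(), config,
                        seed = fold_seed)
      identical(rerun$predictions, cv_full$folds[["r1_f1"]]$predictions)
    })
  }
  list(full = cv_full, control = cv_control,
       auc_full = cv_full$summary$mean, auc_control = cv_control$summary$mean,
       deterministic = deterministic, timings_s = timings)
}
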