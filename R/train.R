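# Repeated stratified cross-validation driver: builds per-fold sample pools,
# pretrains the convolutional branches on balanced patch pools, fine-tunes the
# MLP head at the target prevalence on frozen embeddings, and evaluates pooled
# voxel-wise weighted ROC AUC on the held-out patients.

#' @keywords internal
patch_offset_vector <- function(dp, hw) {
  og <- as.matrix(expand.grid(i = -hw:hw, j = -hw:hw, k = -hw:hw))
  as.integer(og[, 3] * dp[1] * dp[2] + og[, 2] * dp[1] + og[, 1])
}

#' Standardized, zero-padded channel stack for one branch
#'
#' Pads each standardized channel volume by `pad` voxels of zeros (the
#' post-standardization mean) on every side, so valid convolutions over the
#' padded stack align the final embedding with the original voxel grid.
#'
#' @param patient A `patient_features`.
#' @param branch_features,location Channel names.
#' @param stats Persisted `feature_stats`.
#' @param pad Pad width in voxels.
#' @return List: `x` (matrix (prod(dims) x channels)), `dims` (padded shape).
#' @export
padded_branch_stack <- function(patient, branch_features, location, stats,
                                pad) {
  d <- patient$grid$shape
  dp <- d + 2L * pad
  nms <- c(branch_features, location)
  x <- matrix(0, prod(dp), length(nms))
  core <- as.vector(outer(pad + seq_len(d[1]),
                          (pad + seq_len(d[2]) - 1L) * dp[1], `+`))
  core <- as.vector(outer(core, (pad + seq_len(d[3]) - 1L) * dp[1] * dp[2],
                          `+`))
  for (j in seq_along(nms)) {
    nm <- nms[j]
    v <- if (nm %in% names(patient$features)) patient$features[[nm]] else
      patient$location[[nm]]
    x[core, j] <- standardize_value(as.vector(v), stats, nm)
  }
  list(x = x, dims = dp, core = core)
}

#' @keywords internal
patch_rows_for_centres <- function(centres, d, dp, pad) {
  ijk <- arrayInd(centres, d)
  cp <- as.integer((ijk[, 1] + pad) +
                     (ijk[, 2] + pad - 1L) * dp[1] +
                     (ijk[, 3] + pad - 1L) * dp[1] * dp[2])
  offs <- patch_offset_vector(dp, pad)
  as.vector(outer(offs, cp, `+`))
}

#' @keywords internal
stratified_centres <- function(label, weight, mask, n_pos, n_neg, seed) {
  pos <- which(mask & label > 0)
  neg <- which(mask & label <= 0)
  with_seed(seed, {
    list(pos = if (length(pos) > n_pos) sort(sample(pos, n_pos)) else pos,
         neg = if (length(neg) > n_neg) sort(sample(neg, n_neg)) else neg)
  })
}

#' @keywords internal
pool_allocation <- function(counts, total) {
  # proportional allocation with largest-remainder rounding
  if (sum(counts) <= total) return(counts)
  share <- counts * total / sum(counts)
  n <- floor(share)
  rem <- total - sum(n)
  if (rem > 0) {
    o <- order(share - n, decreasing = TRUE)[seq_len(rem)]
    n[o] <- n[o] + 1L
  }
  pmin(as.integer(n), counts)
}

#' Assemble per-fold patch and voxel pools
#'
#' Samples, per patient, class-stratified voxel centres within the prostate:
#' a balanced pretraining pool (capped positives, equal negatives), a
#' fine-tuning pool holding the same positives plus negatives to reach the
#' fine-tune cap, and a validation pool (all positives up to the cap plus
#' negatives). Pools are shared by all branches.
#'
#' @param patients List of `patient_features`.
#' @param ids Patient indices entering the pools.
#' @param n_pos_total,n_total,purpose Pool sizing: balanced (`pretrain`) or
#'   capped total (`finetune`, `val`).
#' @param seed Integer seed.
#' @return List per patient id: `centres`, `y`, `w`.
#' @export
build_pools <- function(patients, ids, n_pos_total, n_total,
                        purpose = c("pretrain", "finetune", "val"),
                        seed = 1L) {
  purpose <- match.arg(purpose)
  pos_counts <- vapply(ids, function(i) {
    p <- patients[[i]]
    sum(p$reference$label[p$prostate_mask] > 0)
  }, 1L)
  neg_counts <- vapply(ids, function(i) {
    p <- patients[[i]]
    sum(p$reference$label[p$prostate_mask] <= 0)
  }, 1L)
  n_pos <- pool_allocation(pos_counts, n_pos_total)
  n_neg_total <- max(n_total - sum(n_pos), sum(n_pos))
  n_neg <- pool_allocation(neg_counts, n_neg_total)
  out <- vector("list", length(ids))
  names(out) <- as.character(ids)
  for (j in seq_along(ids)) {
    i <- ids[j]
    p <- patients[[i]]
    sc <- stratified_centres(p$reference$label, p$reference$weight,
                             p$prostate_mask, n_pos[j], n_neg[j],
                             derive_seed(seed, paste0("pool_", purpose, "_", i)))
    centres <- c(sc$pos, sc$neg)
    out[[j]] <- list(centres = centres,
                     y = as.numeric(p$reference$label[centres] > 0),
                     w = p$reference$weight[centres])
  }
  out
}

#' @keywords internal
cached_stack <- function(patients, i, branch_features, location, stats, pad,
                         cache = NULL) {
  if (is.null(cache)) {
    return(padded_branch_stack(patients[[i]], branch_features, location,
                               stats, pad))
  }
  key <- paste(i, paste(branch_features, collapse = ","), sep = "|")
  got <- cache[[key]]
  if (is.null(got)) {
    got <- padded_branch_stack(patients[[i]], branch_features, location,
                               stats, pad)
    cache[[key]] <- got
  }
  got
}

#' @keywords internal
pool_patches <- function(patients, pools, branch_features, location, stats,
                         pad, cache = NULL) {
  xs <- vector("list", length(pools))
  for (j in seq_along(pools)) {
    i <- as.integer(names(pools)[j])
    pb <- cached_stack(patients, i, branch_features, location, stats, pad,
                       cache)
    rows <- patch_rows_for_centres(pools[[j]]$centres,
                                   patients[[i]]$grid$shape, pb$dims, pad)
    xs[[j]] <- pb$x[rows, , drop = FALSE]
  }
  list(x = do.call(rbind, xs),
       y = unlist(lapply(pools, `[[`, "y"), use.names = FALSE),
       w = unlist(lapply(pools, `[[`, "w"), use.names = FALSE))
}

#' @keywords internal
branch_embed_patches <- function(params, g, x, spec, chunk = 512L) {
  n_sp <- spec$patch^3
  n <- nrow(x) / n_sp
  n_layers <- length(spec$conv_widths)
  pd <- rep(spec$patch, 3L)
  out <- matrix(0, n, spec$embedding)
  s <- 1L
  while (s <= n) {
    e <- min(s + chunk - 1L, n)
    rows <- ((s - 1L) * n_sp + 1L):(e * n_sp)
    out[s:e, ] <- branch_forward(params, g, x[rows, , drop = FALSE], pd,
                                 e - s + 1L, n_layers)$out
    s <- e + 1L
  }
  out
}

#' @keywords internal
embed_pool <- function(params, spec, patients, pools, stats, pad,
                       cache = NULL) {
  embs <- lapply(names(spec$branches), function(g) {
    px <- pool_patches(patients, pools, spec$branches[[g]], spec$location,
                       stats, pad, cache)
    branch_embed_patches(params, g, px$x, spec)
  })
  X <- do.call(cbind, embs)
  if (length(spec$clinical)) {
    cl <- do.call(rbind, lapply(seq_along(pools), function(j) {
      i <- as.integer(names(pools)[j])
      matrix(clinical_row(patients[[i]], spec$clinical, stats),
             length(pools[[j]]$centres), length(spec$clinical), byrow = TRUE)
    }))
    X <- cbind(X, cl)
  }
  list(x = X,
       y = unlist(lapply(pools, `[[`, "y"), use.names = FALSE),
       w = unlist(lapply(pools, `[[`, "w"), use.names = FALSE))
}

#' Voxel-wise probability volume for one patient
#'
#' Runs every branch fully convolutionally over the zero-padded standardized
#' stack (so each voxel receives its embedding) and applies the MLP head.
#'
#' @param model A trained `model_bundle`.
#' @param patient A `patient_features`.
#' @param stats Persisted `feature_stats`.
#' @return 3D array of csPCa probabilities on the patient grid.
#' @export
predict_volume <- function(model, patient, stats) {
  spec <- model$spec
  pad <- (spec$patch - 1L) %/% 2L
  n_layers <- length(spec$conv_widths)
  embs <- lapply(names(spec$branches), function(g) {
    pb <- padded_branch_stack(patient, spec$branches[[g]], spec$location,
                              stats, pad)
    branch_forward(model$params, g, pb$x, pb$dims, 1L, n_layers)$out
  })
  X <- do.call(cbind, embs)
  if (length(spec$clinical)) {
    X <- cbind(X, matrix(clinical_row(patient, spec$clinical, stats),
                         nrow(X), length(spec$clinical), byrow = TRUE))
  }
  array(mlp_forward(model$params, X)$p, dim = patient$grid$shape)
}

#' Control architecture: location channels only
#'
#' Same conv + MLP scaffold restricted to a single branch whose input is just
#' the three location channels, with no clinical scalars: it can only learn
#' where csPCa tends to occur, not what the tissue looks like.
#'
#' @inheritParams architecture_spec
#' @return An `architecture_spec`.
#' @export
control_location_spec <- function(conv_widths = c(8L, 12L, 16L),
                                  mlp_hidden = c(120L, 100L)) {
  architecture_spec(branches = list(loc = character(0)),
                    conv_widths = conv_widths, mlp_hidden = mlp_hidden,
                    clinical = character(0), expected_param_range = NULL)
}

#' Train and evaluate one cross-validation fold
#'
#' Computes fold-scoped standardization statistics, builds the shared sample
#' pools, pretrains each branch on balanced patches, fine-tunes the MLP on
#' frozen embeddings, then scores every prostate voxel of the held-out
#' patients and reports the pooled confidence-weighted ROC AUC.
#'
#' @param patients List of `patient_features`.
#' @param train_ids,val_ids Patient indices.
#' @param spec An [architecture_spec].
#' @param config A [train_config].
#' @param stats Optional precomputed `feature_stats` (leakage mode
#'   `entire_dataset`); computed from `train_ids` when NULL.
#' @param seed Integer fold seed (drives initialisation, pools, batching).
#' @param verbose Print stage progress.
#' @return A `fold_result`: `model`, `stats`, `val_auc`, per-stage epoch
#'   counts, `predictions` (per val patient: scores, labels, weights, zones
#'   over prostate voxels).
#' @export
run_fold <- function(patients, train_ids, val_ids, spec = architecture_spec(),
                     config = train_config(), stats = NULL, seed = 1L,
                     verbose = FALSE) {
  stopifnot(length(train_ids) >= 2L, length(val_ids) >= 1L)
  pad <- (spec$patch - 1L) %/% 2L
  if (is.null(stats)) {
    stats <- compute_feature_stats(patients, train_ids,
                                   stats_scope = "train_folds_only")
  }
  cfg <- config
  cfg$seed <- derive_seed(seed, "train")

  pre_pool <- build_pools(patients, train_ids, cfg$pretrain_pos_cap,
                          2L * cfg$pretrain_pos_cap, "pretrain",
                          derive_seed(seed, "pre"))
  fine_pool <- build_pools(patients, train_ids, cfg$pretrain_pos_cap,
                           cfg$finetune_cap, "finetune",
                           derive_seed(seed, "fine"))
  val_pool <- build_pools(patients, val_ids, cfg$val_cap %/% 4L, cfg$val_cap,
                          "val", derive_seed(seed, "valpool"))
  # smaller balanced pool for the per-epoch branch early-stopping evaluation
  pre_val_pool <- build_pools(patients, val_ids, cfg$pretrain_val_cap %/% 2L,
                              cfg$pretrain_val_cap, "val",
                              derive_seed(seed, "prevalpool"))

  model <- build_model(spec, seed = derive_seed(seed, "model"))
  params <- model$params
  stack_cache <- new.env(parent = emptyenv())
  branch_info <- list()
  for (g in names(spec$branches)) {
    tr <- pool_patches(patients, pre_pool, spec$branches[[g]], spec$location,
                       stats, pad, stack_cache)
    va <- pool_patches(patients, pre_val_pool, spec$branches[[g]],
                       spec$location, stats, pad, stack_cache)
    cfg_g <- cfg
    cfg_g$seed <- derive_seed(seed, paste0("branch_", g))
    pt <- pretrain_branch(params, g, tr, va, spec, cfg_g)
    params <- pt$params
    branch_info[[g]] <- list(val_auc = pt$val_auc, epochs = pt$epochs_run)
    if (verbose) message(sprintf("  branch %-7s val AUC %.3f (%d epochs)",
                                 g, pt$val_auc, pt$epochs_run))
  }

  ftr <- embed_pool(params, spec, patients, fine_pool, stats, pad,
                    stack_cache)
  fva <- embed_pool(params, spec, patients, val_pool, stats, pad, stack_cache)
  cfg_m <- cfg
  cfg_m$seed <- derive_seed(seed, "mlp")
  ft <- finetune_mlp(params, ftr, fva, spec, cfg_m)
  model$params <- ft$params
  if (verbose) message(sprintf("  mlp val AUC %.3f (%d epochs)",
                               ft$val_auc, ft$epochs_run))

  predictions <- lapply(val_ids, function(i) {
    p <- patients[[i]]
    prob <- predict_volume(model, p, stats)
    idx <- which(p$prostate_mask)
    list(patient = p$patient_id, scores = prob[idx],
         labels = as.numeric(p$reference$label[idx] > 0),
         weights = p$reference$weight[idx],
         zones = ifelse(p$pz_mask[idx], "pz", "tz"))
  })
  sc <- unlist(lapply(predictions, `[[`, "scores"), use.names = FALSE)
  lb <- unlist(lapply(predictions, `[[`, "labels"), use.names = FALSE)
  wt <- unlist(lapply(predictions, `[[`, "weights"), use.names = FALSE)
  val_auc <- as.numeric(weighted_roc_auc(sc, lb, wt)$auc)
  structure(list(model = model, stats = stats, val_auc = val_auc,
                 branch_info = branch_info, mlp_epochs = ft$epochs_run,
                 predictions = predictions, val_ids = val_ids),
            class = "fold_result")
}

#' Repeated stratified cross-validation
#'
#' For each repeat, patients are dealt into lesion-burden-stratified folds;
#' each fold is trained with [run_fold] and evaluated on its held-out
#' patients. Every random draw derives from `seed`, the repeat and the fold,
#' so a rerun is bit-for-bit reproducible.
#'
#' @param patients List of `patient_features`.
#' @param spec An [architecture_spec].
#' @param config A [train_config].
#' @param n_folds,n_repeats Cross-validation layout (default 7 x 2).
#' @param stats_scope `"train_folds_only"` (leakage-safe, per-fold statistics)
#'   or `"entire_dataset"` (statistics pooled over all patients once).
#' @param seed Integer seed.
#' @param verbose Print fold progress.
#' @return A `crossval_result`: `folds` (per repeat x fold `fold_result`s
#'   without models), `fold_aucs` data.frame, `summary` from
#'   [repeated_cv_aggregate], `plan` per repeat.
#' @export
run_crossval <- function(patients, spec = architecture_spec(),
                         config = train_config(), n_folds = 7L,
                         n_repeats = 2L, stats_scope = "train_folds_only",
                         seed = 1L, verbose = FALSE, keep_models = FALSE) {
  stopifnot(length(patients) >= n_folds)
  stats_scope <- match.arg(stats_scope,
                           c("train_folds_only", "entire_dataset"))
  burden <- vapply(patients, function(p)
    sum(p$reference$label[p$prostate_mask] > 0), 1)
  global_stats <- if (stats_scope == "entire_dataset") {
    compute_feature_stats(patients, stats_scope = "entire_dataset")
  } else NULL

  plans <- list()
  folds <- list()
  rows <- list()
  for (r in seq_len(n_repeats)) {
    plan <- make_folds(seq_along(patients), burden, k = n_folds,
                       seed = derive_seed(seed, paste0("rep", r)))
    plans[[r]] <- plan
    for (f in seq_len(n_folds)) {
      val_ids <- which(plan$fold == f)
      train_ids <- which(plan$fold != f)
      if (!length(val_ids)) next
      if (verbose) message(sprintf("repeat %d fold %d (%d train / %d val)",
                                   r, f, length(train_ids), length(val_ids)))
      fr <- run_fold(patients, train_ids, val_ids, spec, config,
                     stats = global_stats,
                     seed = derive_seed(seed, paste0("rep", r, "_fold", f)),
                     verbose = verbose)
      if (!keep_models) fr$model <- NULL
      key <- sprintf("r%d_f%d", r, f)
      folds[[key]] <- fr
      rows[[key]] <- data.frame(repeat_ = r, fold = f, auc = fr$val_auc)
      if (verbose) message(sprintf("  fold AUC %.3f", fr$val_auc))
    }
  }
  fold_aucs <- do.call(rbind, rows)
  rownames(fold_aucs) <- NULL
  structure(list(folds = folds, fold_aucs = fold_aucs,
                 summary = repeated_cv_aggregate(fold_aucs$auc),
                 plan = plans, stats_scope = stats_scope, seed = seed),
            class = "crossval_result")
}

#' Pool held-out predictions of a cross-validation run
#'
#' @param cv A `crossval_result`.
#' @return data.frame (repeat_, fold, patient, score, label, weight, zone),
#'   one row per held-out prostate voxel.
#' @export
pooled_predictions <- function(cv) {
  out <- list()
  for (key in names(cv$folds)) {
    fr <- cv$folds[[key]]
    meta <- cv$fold_aucs[match(key, sprintf("r%d_f%d", cv$fold_aucs$repeat_,
                                            cv$fold_aucs$fold)), ]
    for (pr in fr$predictions) {
      out[[length(out) + 1L]] <- data.frame(
        repeat_ = meta$repeat_, fold = meta$fold, patient = pr$patient,
        score = pr$scores, label = pr$labels, weight = pr$weights,
        zone = pr$zones, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
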