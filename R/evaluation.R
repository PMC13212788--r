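# Confidence-weighted ROC analysis: weighted Mann-Whitney AUC with the 1/2
# tie convention, the weighted ROC curve, Youden's operating point, per-zone
# stratification and repeated-CV aggregation.

#' Confidence-weighted ROC curve and AUC
#'
#' `AUC = sum_{i in pos} sum_{j in neg} w_i w_j (1[s_i > s_j] + 1/2 1[s_i =
#' s_j]) / (W_pos W_neg)`, computed in `O(n log n)` from the weighted
#' cumulative curve; ties between scores contribute with the trapezoid (1/2)
#' convention.
#'
#' @param scores Numeric scores (higher = more suspicious).
#' @param labels Binary labels.
#' @param weights Positive voxel weights (default 1).
#' @return A `roc_result`: `auc`, `curve` (data.frame threshold, sens, spec),
#'   `n_pos_eff`, `n_neg_eff`.
#' @export
weighted_roc_auc <- function(scores, labels, weights = rep(1, length(scores))) {
  ok <- is.finite(scores) & is.finite(labels) & is.finite(weights)
  scores <- scores[ok]; labels <- labels[ok]; weights <- weights[ok]
  stopifnot(length(scores) > 0, all(weights > 0))
  pos <- labels > 0
  if (!any(pos) || all(pos)) stop("both classes must be present")
  w_pos <- sum(weights[pos]); w_neg <- sum(weights[!pos])

  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- pos[o]; w <- weights[o]
  # collapse tied scores into single curve steps
  grp <- cumsum(!duplicated(s))
  tp_step <- tapply(w * y, grp, sum)
  fp_step <- tapply(w * !y, grp, sum)
  thr <- s[!duplicated(s)]
  tp <- cumsum(tp_step); fp <- cumsum(fp_step)
  # trapezoid over the (fp, tp) curve implements the 1/2 tie convention
  auc <- sum((tp - tp_step / 2) * fp_step) / (w_pos * w_neg)
  curve <- data.frame(threshold = as.numeric(thr),
                      sens = as.numeric(tp) / w_pos,
                      spec = 1 - as.numeric(fp) / w_neg)
  structure(list(auc = auc, curve = curve, n_pos_eff = w_pos,
                 n_neg_eff = w_neg), class = "roc_result")
}

#' Youden operating point
#'
#' Maximises `J = sens + spec - 1` over the ROC curve; ties broken toward the
#' higher sensitivity.
#'
#' @param roc A `roc_result`.
#' @return List: `sensitivity`, `specificity`, `threshold`, `J`.
#' @export
youden_point <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  cv <- roc$curve
  J <- cv$sens + cv$spec - 1
  best <- which(J >= max(J) - 1e-12)
  best <- best[which.max(cv$sens[best])]
  list(sensitivity = cv$sens[best], specificity = cv$spec[best],
       threshold = cv$threshold[best], J = J[best])
}

#' Zone-stratified weighted ROC AUCs
#'
#' Computes the weighted AUC over the whole prostate and restricted to the
#' peripheral and transition zones. A zone missing one class is reported as
#' `NA`, not 0.5.
#'
#' @param scores,labels,weights Voxel vectors (already masked to the
#'   prostate), or 3D arrays alongside array `zones`.
#' @param pz,tz Logical vectors/arrays marking the zones.
#' @return Data frame: zone ("whole", "pz", "tz"), auc, n_pos_eff, n_neg_eff.
#' @export
zone_stratified_eval <- function(scores, labels, weights, pz, tz) {
  one <- function(sel) {
    s <- scores[sel]; y <- labels[sel]; w <- weights[sel]
    ok <- is.finite(s) & is.finite(y)
    if (!any(y[ok] > 0) || all(y[ok] > 0)) {
      return(c(auc = NA_real_, n_pos_eff = NA_real_, n_neg_eff = NA_real_))
    }
    r <- weighted_roc_auc(s[ok], y[ok], w[ok])
    c(auc = r$auc, n_pos_eff = r$n_pos_eff, n_neg_eff = r$n_neg_eff)
  }
  rows <- rbind(whole = one(rep(TRUE, length(scores))), pz = one(as.logical(pz)),
                tz = one(as.logical(tz)))
  data.frame(zone = rownames(rows), rows, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Aggregate AUCs over repeated cross-validation
#'
#' @param aucs Numeric vector of per-(repeat, fold) AUCs.
#' @return List: `mean`, `sd`, `ci_low`, `ci_high` (normal approximation,
#'   95%), `n`.
#' @export
repeated_cv_aggregate <- function(aucs) {
  aucs <- aucs[is.finite(aucs)]
  stopifnot(length(aucs) >= 2L)
  m <- mean(aucs); s <- stats::sd(aucs); n <- length(aucs)
  half <- 1.96 * s / sqrt(n)
  list(mean = m, sd = s, ci_low = m - half, ci_high = m + half, n = n)
}

#' Zone-stratified AUC table for a cross-validation run
#'
#' Computes whole-gland, PZ and TZ confidence-weighted AUCs per
#' (repeat, fold) from the held-out predictions, then aggregates each zone
#' over folds with [repeated_cv_aggregate].
#'
#' @param cv A `crossval_result` from [run_crossval].
#' @return Data frame: zone, auc (mean over folds), ci_low, ci_high, n_folds.
#' @export
crossval_zone_table <- function(cv) {
  per_fold <- lapply(cv$folds, function(fr) {
    sc <- unlist(lapply(fr$predictions, `[[`, "scores"), use.names = FALSE)
    lb <- unlist(lapply(fr$predictions, `[[`, "labels"), use.names = FALSE)
    wt <- unlist(lapply(fr$predictions, `[[`, "weights"), use.names = FALSE)
    zn <- unlist(lapply(fr$predictions, `[[`, "zones"), use.names = FALSE)
    zone_stratified_eval(sc, lb, wt, zn == "pz", zn == "tz")
  })
  zones <- c("whole", "pz", "tz")
  rows <- lapply(zones, function(z) {
    aucs <- vapply(per_fold, function(tb) tb$auc[tb$zone == z], 1)
    ag <- repeated_cv_aggregate(aucs)
    data.frame(zone = z, auc = ag$mean, ci_low = ag$ci_low,
               ci_high = ag$ci_high, n_folds = ag$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
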