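#' Per-study 2x2 table at a positivity threshold
#'
#' Cross-classifies one study's patients (complete cases on test result and
#' disease status) against the positivity rule `test_result >= threshold`:
#' TP diseased positives, FN diseased negatives, FP nondiseased positives,
#' TN nondiseased negatives.
#'
#' @param data An `ipd_dataset`.
#' @param study A study id present in the data.
#' @param threshold Positivity threshold (finite, or `-Inf`/`Inf`).
#' @param invert Reverse the positivity direction (lower = positive).
#' @return A one-row data frame: `study_id`, `threshold`, `TP`, `FN`,
#'   `FP`, `TN`.
#' @export
contingency_table <- function(data, study, threshold, invert = FALSE) {
  v <- test_by_class(data, study)
  pos_d <- if (invert) v$diseased <= threshold else v$diseased >= threshold
  pos_n <- if (invert) v$nondiseased <= threshold else v$nondiseased >= threshold
  data.frame(study_id = study, threshold = threshold,
             TP = sum(pos_d), FN = sum(!pos_d),
             FP = sum(pos_n), TN = sum(!pos_n))
}

#' 2x2 tables for every study under a resolved threshold specification
#'
#' @param data An `ipd_dataset`.
#' @param spec A resolved [threshold_spec()] (see [resolve_thresholds()]);
#'   an unresolved spec is resolved first.
#' @return A data frame with one row per analyzable study:
#'   `study_id`, `threshold`, `TP`, `FN`, `FP`, `TN`.
#' @export
contingency_tables <- function(data, spec) {
  if (is.null(spec$resolved)) spec <- resolve_thresholds(data, spec)
  out <- do.call(rbind, lapply(names(spec$resolved), function(i) {
    contingency_table(data, as.integer(i), spec$resolved[[i]],
                      invert = spec$invert)
  }))
  rownames(out) <- NULL
  out
}

# Clopper-Pearson exact two-sided CI for a binomial proportion.
ci_clopper_pearson <- function(x, n, level = 0.95) {
  a <- (1 - level) / 2
  lo <- if (x == 0) 0 else qbeta(a, x, n - x + 1)
  hi <- if (x == n) 1 else qbeta(1 - a, x + 1, n - x)
  c(lo, hi)
}

#' Full accuracy panel for a 2x2 table
#'
#' Computes sensitivity, specificity, positive and negative predictive
#' values with Clopper-Pearson exact confidence intervals, and the ratio
#' measures LR+, LR-, and the diagnostic odds ratio with log-scale Wald
#' intervals. If any cell is zero, a 0.5 continuity correction is applied
#' to all four cells *for the ratio measures only*; the proportion measures
#' are reported from the raw cells.
#'
#' @param table A one-row data frame (or list) with `TP`, `FN`, `FP`, `TN`.
#' @param level Confidence level (default 0.95).
#' @return A one-row data frame with point estimates and `_low`/`_high`
#'   CI bounds for `sens`, `spec`, `ppv`, `npv`, `lr_pos`, `lr_neg`, `dor`,
#'   and a logical `continuity_corrected`.
#' @export
accuracy_panel <- function(table, level = 0.95) {
  tp <- table$TP; fn <- table$FN; fp <- table$FP; tn <- table$TN
  if (tp + fn + fp + tn == 0) {
    ipd_abort("empty 2x2 table: all four cells are zero", "ipddta_empty_error")
  }
  z <- qnorm(1 - (1 - level) / 2)

  prop <- function(x, n) {
    ci <- ci_clopper_pearson(x, n, level)
    c(est = x / n, low = ci[1], high = ci[2])
  }
  se <- prop(tp, tp + fn); sp <- prop(tn, tn + fp)
  ppv <- prop(tp, tp + fp); npv <- prop(tn, tn + fn)

  corrected <- any(c(tp, fn, fp, tn) == 0)
  if (corrected) { tpc <- tp + 0.5; fnc <- fn + 0.5; fpc <- fp + 0.5; tnc <- tn + 0.5 }
  else { tpc <- tp; fnc <- fn; fpc <- fp; tnc <- tn }
  sec <- tpc / (tpc + fnc); spc <- tnc / (tnc + fpc)

  lrp <- sec / (1 - spc)
  se_log_lrp <- sqrt(1 / tpc - 1 / (tpc + fnc) + 1 / fpc - 1 / (fpc + tnc))
  lrn <- (1 - sec) / spc
  se_log_lrn <- sqrt(1 / fnc - 1 / (tpc + fnc) + 1 / tnc - 1 / (fpc + tnc))
  dor <- (tpc * tnc) / (fpc * fnc)
  se_log_dor <- sqrt(1 / tpc + 1 / fnc + 1 / fpc + 1 / tnc)

  ratio_ci <- function(est, se_log) c(est * exp(-z * se_log), est * exp(z * se_log))
  lrp_ci <- ratio_ci(lrp, se_log_lrp)
  lrn_ci <- ratio_ci(lrn, se_log_lrn)
  dor_ci <- ratio_ci(dor, se_log_dor)

  out <- data.frame(
    sens = se[["est"]], sens_low = se[["low"]], sens_high = se[["high"]],
    spec = sp[["est"]], spec_low = sp[["low"]], spec_high = sp[["high"]],
    ppv = ppv[["est"]], ppv_low = ppv[["low"]], ppv_high = ppv[["high"]],
    npv = npv[["est"]], npv_low = npv[["low"]], npv_high = npv[["high"]],
    lr_pos = lrp, lr_pos_low = lrp_ci[1], lr_pos_high = lrp_ci[2],
    lr_neg = lrn, lr_neg_low = lrn_ci[1], lr_neg_high = lrn_ci[2],
    dor = dor, dor_low = dor_ci[1], dor_high = dor_ci[2],
    continuity_corrected = corrected)
  if (!is.null(table$study_id)) out <- cbind(study_id = table$study_id, out)
  out
}

#' Empirical AUC with DeLong standard error
#'
#' The empirical area under the ROC curve is the Mann-Whitney two-sample
#' statistic: the proportion of (diseased, nondiseased) pairs in which the
#' diseased value is larger, counting ties as one half. The standard error
#' is DeLong's, from the variances of the per-subject placement components;
#' the confidence interval is clipped to \[0, 1\].
#'
#' For a degenerate sample (AUC exactly 0 or 1) the DeLong variance
#' collapses to zero; a floor based on the Hanley-McNeil variance at an AUC
#' moved half a pair off the boundary is substituted and the result is
#' flagged.
#'
#' @param diseased,nondiseased Numeric vectors of test values.
#' @param level Confidence level (default 0.95).
#' @return A list: `auc`, `se`, `ci_low`, `ci_high`, `flagged` (TRUE when
#'   the SE floor was used), and `auc_adj` (the off-boundary AUC used for
#'   the floor; equals `auc` otherwise).
#' @export
empirical_auc <- function(diseased, nondiseased, level = 0.95) {
  x <- diseased[!is.na(diseased)]
  y <- nondiseased[!is.na(nondiseased)]
  nd <- length(x); nn <- length(y)
  if (!nd || !nn) {
    ipd_abort("AUC undefined: one group is empty", "ipddta_undefined_error")
  }
  r_all <- rank(c(x, y))
  auc <- (sum(r_all[seq_len(nd)]) - nd * (nd + 1) / 2) / (nd * nn)
  # placement components (midranks handle ties with weight 1/2)
  v10 <- (r_all[seq_len(nd)] - rank(x)) / nn
  v01 <- 1 - (r_all[nd + seq_len(nn)] - rank(y)) / nd
  s10 <- if (nd > 1) var(v10) else 0
  s01 <- if (nn > 1) var(v01) else 0
  se <- sqrt(s10 / nd + s01 / nn)

  flagged <- FALSE
  auc_adj <- auc
  if (auc %in% c(0, 1) || se == 0) {
    flagged <- TRUE
    npairs <- nd * nn
    auc_adj <- if (auc >= 0.5) (npairs - 0.5) / npairs else 0.5 / npairs
    a <- auc_adj
    q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
    se <- sqrt((a * (1 - a) + (nd - 1) * (q1 - a^2) + (nn - 1) * (q2 - a^2)) /
                 (nd * nn))
  }
  z <- qnorm(1 - (1 - level) / 2)
  list(auc = auc, se = se,
       ci_low = max(0, auc - z * se), ci_high = min(1, auc + z * se),
       flagged = flagged, auc_adj = auc_adj)
}

#' Empirical ROC curve points for one study
#'
#' Coordinates of the empirical (step-function) ROC curve: one point per
#' distinct observed test value, thresholded at `>=`, plus the (0,0) and
#' (1,1) endpoints.
#'
#' @param diseased,nondiseased Numeric vectors of test values.
#' @return A data frame with `threshold`, `fpr`, `tpr`, ordered by
#'   increasing `fpr` (decreasing threshold).
#' @export
roc_points <- function(diseased, nondiseased) {
  x <- diseased[!is.na(diseased)]; y <- nondiseased[!is.na(nondiseased)]
  thr <- sort(unique(c(x, y)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(x >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(y >= t), numeric(1))
  data.frame(threshold = c(Inf, thr, -Inf),
             fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
}
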