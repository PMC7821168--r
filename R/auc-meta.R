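#' Per-study empirical AUCs
#'
#' Computes the empirical (Mann-Whitney) AUC with DeLong standard error for
#' every analyzable study (both disease classes present). Studies with only
#' one class are excluded with a warning; studies with a degenerate AUC
#' (exactly 0 or 1) are retained with the documented SE floor and flagged
#' (see [empirical_auc()]).
#'
#' @param data An `ipd_dataset`.
#' @param level Confidence level (default 0.95).
#' @return Data frame with `study_id`, `auc`, `se`, `ci_low`, `ci_high`,
#'   `flagged`, `auc_adj`, `n_diseased`, `n_nondiseased`.
#' @export
study_aucs <- function(data, level = 0.95) {
  ids <- analyzable_studies(data)
  skipped <- setdiff(sort(unique(data$study_id)), ids)
  if (length(skipped)) {
    ipd_warn(sprintf("study id %s excluded from AUC analysis (single disease class)",
                     paste(skipped, collapse = ", ")),
             "ipddta_single_class_warning")
  }
  if (!length(ids)) ipd_abort("no usable study for AUC analysis", "ipddta_empty_error")
  out <- do.call(rbind, lapply(ids, function(i) {
    v <- test_by_class(data, i)
    a <- empirical_auc(v$diseased, v$nondiseased, level = level)
    data.frame(study_id = i, auc = a$auc, se = a$se,
               ci_low = a$ci_low, ci_high = a$ci_high,
               flagged = a$flagged, auc_adj = a$auc_adj,
               n_diseased = length(v$diseased),
               n_nondiseased = length(v$nondiseased))
  }))
  rownames(out) <- NULL
  out
}

#' Fixed- and random-effects meta-analysis of AUC
#'
#' Pools per-study AUCs by inverse-variance weighting: a fixed-effect
#' (common-effect) estimate with weights `1/se^2` and a DerSimonian-Laird
#' random-effects estimate with weights `1/(se^2 + tau^2)`, together with
#' the heterogeneity statistics Q, I^2 = max(0, (Q - (k-1))/Q) and tau^2.
#' Pooling can be done on the raw AUC scale (confidence limits clipped to
#' \[0,1\] with a warning when they spill over) or on the logit scale with
#' delta-method standard errors, back-transformed for reporting. On the
#' logit scale, boundary AUCs (exactly 0 or 1) enter through their
#' continuity-adjusted values.
#'
#' @param studies Data frame from [study_aucs()] (needs `auc`, `se`;
#'   optionally `study_id`, `flagged`, `auc_adj`).
#' @param scale `"raw"` (default) or `"logit"`.
#' @param level Confidence level (default 0.95).
#' @return Object of class `auc_meta`: list with `studies` (including
#'   normalized fixed/random weights), `pooled_fixed` and `pooled_random`
#'   (each `estimate`, `se`, `ci_low`, `ci_high`), `tau2`, `Q`, `I2`, `k`,
#'   `scale`, `level`.
#' @export
pool_auc <- function(studies, scale = c("raw", "logit"), level = 0.95) {
  scale <- match.arg(scale)
  if (nrow(studies) < 2) {
    ipd_abort("pooling requires at least 2 studies", "ipddta_insufficient_data_error")
  }
  if (any(!is.finite(studies$se) | studies$se <= 0)) {
    ipd_abort("every study must have a finite positive standard error",
              "ipddta_validation_error")
  }
  auc <- studies$auc
  if (scale == "logit") {
    a <- if ("auc_adj" %in% names(studies)) studies$auc_adj else auc
    a <- pmin(pmax(a, 1e-12), 1 - 1e-12)
    yi <- qlogis(a)
    sei <- studies$se / (a * (1 - a))   # delta method
  } else {
    yi <- auc
    sei <- studies$se
  }

  fe <- metafor::rma(yi = yi, sei = sei, method = "EE", level = 100 * level)
  re <- metafor::rma(yi = yi, sei = sei, method = "DL", level = 100 * level)

  k <- length(yi)
  Q <- unname(re$QE)
  I2 <- max(0, (Q - (k - 1)) / Q)
  tau2 <- max(0, unname(re$tau2))

  w_fixed <- (1 / sei^2) / sum(1 / sei^2)
  w_random <- (1 / (sei^2 + tau2)) / sum(1 / (sei^2 + tau2))

  if (scale == "raw" &&
      (fe$ci.lb < 0 || fe$ci.ub > 1 || re$ci.lb < 0 || re$ci.ub > 1)) {
    ipd_warn("raw-scale confidence limit outside [0,1]; clipped",
             "ipddta_ci_clipped_warning")
  }
  back <- function(fit) {
    est <- as.numeric(fit$beta); se <- fit$se
    lo <- fit$ci.lb; hi <- fit$ci.ub
    if (scale == "logit") {
      c(estimate = plogis(est), se = se * plogis(est) * (1 - plogis(est)),
        ci_low = plogis(lo), ci_high = plogis(hi))
    } else {
      c(estimate = est, se = se, ci_low = max(0, lo), ci_high = min(1, hi))
    }
  }

  st <- studies
  st$weight_fixed <- w_fixed
  st$weight_random <- w_random
  structure(list(studies = st,
                 pooled_fixed = as.list(back(fe)),
                 pooled_random = as.list(back(re)),
                 tau2 = tau2, Q = Q, I2 = I2, k = k,
                 scale = scale, level = level),
            class = "auc_meta")
}

#' @export
print.auc_meta <- function(x, ...) {
  cat(sprintf("Meta-analysis of AUC (%d studies, %s scale)\n", x$k, x$scale))
  cat(sprintf("  fixed effect : %.4f [%.4f, %.4f]\n",
              x$pooled_fixed$estimate, x$pooled_fixed$ci_low, x$pooled_fixed$ci_high))
  cat(sprintf("  random effect: %.4f [%.4f, %.4f]\n",
              x$pooled_random$estimate, x$pooled_random$ci_low, x$pooled_random$ci_high))
  cat(sprintf("  heterogeneity: Q = %.3f (df = %d), I2 = %.1f%%, tau2 = %.5f\n",
              x$Q, x$k - 1, 100 * x$I2, x$tau2))
  invisible(x)
}

#' Flat CSV-ready table of an AUC meta-analysis
#'
#' @param x An `auc_meta` object.
#' @return Data frame with the per-study rows followed by the two pooled
#'   rows; pooled rows carry `NA` weights.
#' @export
auc_meta_table <- function(x) {
  st <- x$studies
  per <- data.frame(label = paste("Study", st$study_id),
                    auc = st$auc, ci_low = st$ci_low, ci_high = st$ci_high,
                    weight_fixed = st$weight_fixed,
                    weight_random = st$weight_random)
  pooled <- data.frame(
    label = c("Fixed effect", "Random effects"),
    auc = c(x$pooled_fixed$estimate, x$pooled_random$estimate),
    ci_low = c(x$pooled_fixed$ci_low, x$pooled_random$ci_low),
    ci_high = c(x$pooled_fixed$ci_high, x$pooled_random$ci_high),
    weight_fixed = NA, weight_random = NA)
  rbind(per, pooled)
}
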