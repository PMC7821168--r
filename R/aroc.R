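#' Per-study, per-disease-group covariate distribution summaries
#'
#' For a continuous covariate, kernel density estimates (Gaussian kernel,
#' Silverman's rule-of-thumb bandwidth) are computed per study and disease
#' group, ready for ridgeline rendering. For a categorical covariate, level
#' counts and percentages per study and group are returned, ready for a
#' stacked bar chart. A degenerate continuous covariate (a single distinct
#' value) is routed to the categorical path with a warning, where it shows
#' as one 100% level.
#'
#' @param data An `ipd_dataset`.
#' @param covariate Covariate name present in the data.
#' @return Object of class `covariate_distribution`: list with `covariate`,
#'   `type` (`"continuous"` or `"categorical"`), and `summary` -- for
#'   continuous, a data frame `study_id`, `group`, `x`, `density`; for
#'   categorical, `study_id`, `group`, `level`, `count`, `pct`.
#' @export
covariate_distributions <- function(data, covariate) {
  types <- covariate_types(data)
  if (!covariate %in% names(types)) {
    ipd_abort(sprintf("unknown covariate '%s'; available: %s", covariate,
                      paste(names(types), collapse = ", ")),
              "ipddta_lookup_error")
  }
  col <- data[[covariate]]
  type <- types[[covariate]]
  if (type == "continuous" && length(unique(col[!is.na(col)])) < 2) {
    ipd_warn(sprintf("covariate '%s' is constant; summarized as categorical", covariate),
             "ipddta_degenerate_covariate_warning")
    type <- "categorical"
  }
  ids <- sort(unique(data$study_id))
  grp_label <- function(d) ifelse(d == 1, "diseased", "nondiseased")

  if (type == "continuous") {
    rows <- list()
    for (i in ids) for (g in c(1, 0)) {
      v <- col[data$study_id == i & data$disease == g]
      v <- v[!is.na(v)]
      if (length(v) < 2 || length(unique(v)) < 2) next
      d <- density(v, bw = "nrd0", kernel = "gaussian")
      rows[[length(rows) + 1]] <- data.frame(
        study_id = i, group = grp_label(g), x = d$x, density = d$y)
    }
    summary <- do.call(rbind, rows)
  } else {
    lv <- sort(unique(as.character(col[!is.na(col)])))
    rows <- list()
    for (i in ids) for (g in c(1, 0)) {
      v <- as.character(col[data$study_id == i & data$disease == g])
      v <- v[!is.na(v)]
      if (!length(v)) next
      counts <- vapply(lv, function(l) sum(v == l), integer(1))
      rows[[length(rows) + 1]] <- data.frame(
        study_id = i, group = grp_label(g), level = lv,
        count = counts, pct = 100 * counts / length(v),
        stringsAsFactors = FALSE, row.names = NULL)
    }
    summary <- do.call(rbind, rows)
  }
  structure(list(covariate = covariate, type = type, summary = summary),
            class = "covariate_distribution")
}

#' Study-specific linear regressions of test result on a covariate
#'
#' Ordinary least squares of the index-test result on one continuous
#' covariate, fitted separately within each study on complete cases.
#' Studies with fewer than 3 complete cases or zero covariate variance are
#' skipped with a warning.
#'
#' @param data An `ipd_dataset`.
#' @param covariate Name of a continuous covariate.
#' @return Data frame with `study_id`, `intercept`, `slope`, `slope_se`,
#'   `r_squared`, `n`.
#' @export
per_study_regressions <- function(data, covariate) {
  types <- covariate_types(data)
  if (!covariate %in% names(types)) {
    ipd_abort(sprintf("unknown covariate '%s'", covariate), "ipddta_lookup_error")
  }
  if (types[[covariate]] != "continuous") {
    ipd_abort(sprintf("covariate '%s' is categorical; use covariate_distributions() instead",
                      covariate), "ipddta_type_error")
  }
  ids <- sort(unique(data$study_id))
  skipped <- integer(0)
  rows <- list()
  for (i in ids) {
    s <- data[data$study_id == i, , drop = FALSE]
    ok <- !is.na(s$test_result) & !is.na(s[[covariate]])
    y <- s$test_result[ok]; x <- s[[covariate]][ok]
    if (length(y) < 3 || length(unique(x)) < 2) { skipped <- c(skipped, i); next }
    fit <- lm(y ~ x)
    sm <- summary(fit)
    rows[[length(rows) + 1]] <- data.frame(
      study_id = i, intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
      slope_se = sm$coefficients[2, 2], r_squared = sm$r.squared, n = length(y))
  }
  if (length(skipped)) {
    ipd_warn(sprintf("study id %s skipped (n < 3 or constant covariate)",
                     paste(skipped, collapse = ", ")),
             "ipddta_regression_skipped_warning")
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) ipd_abort("no study allowed a regression fit", "ipddta_empty_error")
  rownames(out) <- NULL
  out
}

#' Covariate-adjusted ROC curve (semiparametric placement-value estimator)
#'
#' Adjusts the ROC curve of the pooled IPD for one patient-level covariate.
#' The estimator:
#' 1. fits the linear location model `test_result = b0 + b1 * covariate +
#'    sigma * eps` by least squares in the pooled *nondiseased* sample
#'    (a categorical covariate enters through indicator terms);
#' 2. estimates the residual scale `sigma_hat` with denominator `n - p`;
#' 3. takes `F_hat`, the right-continuous empirical CDF of the
#'    standardized nondiseased residuals;
#' 4. computes, for each diseased subject, the placement value
#'    `U = 1 - F_hat((y - b0 - b1 * x) / sigma_hat)` -- the subject's
#'    standing within the covariate-matched nondiseased population;
#' 5. estimates the adjusted ROC as `AROC(t) = mean(U <= t)` and the
#'    adjusted area as `AAUC = 1 - mean(U)`.
#'
#' The regression pools the nondiseased subjects across studies (no study
#' effects), matching a single-covariate adjustment; if the covariate has
#' no association with the test result, the adjusted ROC reduces to the
#' pooled empirical ROC of the raw test results.
#'
#' @param data An `ipd_dataset`.
#' @param covariate Covariate name (continuous or categorical), or `NULL`
#'   for an intercept-only location model (no adjustment; useful as a
#'   reduction check against the pooled empirical ROC).
#' @return Object of class `aroc_fit`: list with `covariate`,
#'   `coefficients` (nondiseased regression), `sigma_hat`, `resid_ecdf`,
#'   `placement` (data frame `study_id`, `u`), `aauc`, `n_diseased`,
#'   `n_nondiseased`.
#' @export
fit_aroc <- function(data, covariate = NULL) {
  types <- covariate_types(data)
  if (!is.null(covariate) && !covariate %in% names(types)) {
    ipd_abort(sprintf("unknown covariate '%s'", covariate), "ipddta_lookup_error")
  }
  df <- as.data.frame(data)
  ok <- !is.na(df$test_result) & !is.na(df$disease)
  if (!is.null(covariate)) ok <- ok & !is.na(df[[covariate]])
  df <- df[ok, , drop = FALSE]
  if (!is.null(covariate) && types[[covariate]] == "categorical") {
    df[[covariate]] <- factor(df[[covariate]])
  }

  nd <- df[df$disease == 0, , drop = FALSE]
  dd <- df[df$disease == 1, , drop = FALSE]
  if (!nrow(dd)) {
    ipd_abort("no diseased subject with an observed covariate value", "ipddta_empty_error")
  }
  form <- if (is.null(covariate)) test_result ~ 1 else
    stats::reformulate(covariate, response = "test_result")
  X <- stats::model.matrix(stats::delete.response(stats::terms(form)), nd)
  p <- ncol(X)
  if (nrow(nd) < p + 2) {
    ipd_abort("nondiseased sample too small to fit the adjustment regression",
              "ipddta_insufficient_data_error")
  }
  if (qr(X)$rank < p) {
    ipd_abort("adjustment regression design is rank deficient", "ipddta_design_error")
  }
  fit <- lm(form, data = nd)
  sigma_hat <- sqrt(sum(stats::residuals(fit)^2) / (nrow(nd) - p))
  Fhat <- ecdf(stats::residuals(fit) / sigma_hat)

  pred_d <- stats::predict(fit, newdata = dd)
  u <- 1 - Fhat((dd$test_result - pred_d) / sigma_hat)
  structure(list(covariate = covariate %||% "(none)",
                 coefficients = coef(fit), sigma_hat = sigma_hat,
                 resid_ecdf = Fhat,
                 placement = data.frame(study_id = dd$study_id, u = u),
                 aauc = 1 - mean(u),
                 n_diseased = nrow(dd), n_nondiseased = nrow(nd)),
            class = "aroc_fit")
}

#' @export
print.aroc_fit <- function(x, ...) {
  cat(sprintf("Covariate-adjusted ROC fit (covariate: %s)\n", x$covariate))
  cat(sprintf("  nondiseased regression on %d subjects, sigma_hat = %.4f\n",
              x$n_nondiseased, x$sigma_hat))
  cat(sprintf("  AAUC = %.4f (%d diseased subjects)\n", x$aauc, x$n_diseased))
  invisible(x)
}

#' Covariate-adjusted ROC curve on a grid
#'
#' Evaluates `AROC(t) = mean(U <= t)` on a grid of false-positive rates.
#' The value at `t = 0` reports the limit 0 by convention; any placement
#' values equal to 0 (diseased subjects beyond every nondiseased residual)
#' contribute from the first positive grid point onward.
#'
#' @param fit An `aroc_fit`.
#' @param grid Grid of `t` values in \[0, 1\] (default `seq(0, 1, 0.005)`).
#' @return Data frame with `t` and `aroc`, non-decreasing in `t`, with
#'   `aroc = 1` at `t = 1`.
#' @export
aroc_curve <- function(fit, grid = seq(0, 1, by = 0.005)) {
  u <- fit$placement$u
  a <- vapply(grid, function(t) mean(u <= t), numeric(1))
  a[grid == 0] <- 0
  data.frame(t = grid, aroc = a)
}

#' Adjusted analogues of the continuous-analysis summaries
#'
#' Bundles the covariate-adjusted ROC curve and adjusted AUC into the same
#' shape as the unadjusted continuous-analysis outputs, for rendering and
#' export.
#'
#' @param fit An `aroc_fit`.
#' @param grid Grid passed to [aroc_curve()].
#' @return List with `curve` (data frame `t`, `aroc`), `aauc`, and
#'   `summary` (one-row data frame with the AAUC and group sizes).
#' @export
aroc_view <- function(fit, grid = seq(0, 1, by = 0.005)) {
  curve <- aroc_curve(fit, grid)
  list(curve = curve, aauc = fit$aauc,
       summary = data.frame(covariate = fit$covariate, aauc = fit$aauc,
                            n_diseased = fit$n_diseased,
                            n_nondiseased = fit$n_nondiseased))
}
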