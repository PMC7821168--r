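#' Bivariate random-effects model for sensitivity and specificity
#'
#' Fits the standard two-stage summary model for dichotomized diagnostic
#' accuracy data. Stage one computes, per study, the observed logit
#' sensitivity and logit specificity with within-study variances
#' `1/TP + 1/FN` and `1/TN + 1/FP` (0.5 is added to all four cells of any
#' study containing a zero cell). Stage two treats the pair of logits as
#' bivariate normal around study-specific true values, which are themselves
#' bivariate normal across studies with means `(mu_A, mu_B)` and an
#' unstructured between-study covariance; that covariance is estimated by
#' restricted maximum likelihood via [metafor::rma.mv()].
#'
#' @param tables Data frame of per-study 2x2 tables with columns
#'   `study_id`, `TP`, `FN`, `FP`, `TN` (see [contingency_tables()]).
#' @param level Confidence level stored for downstream summaries.
#' @return An object of class `bivariate_fit` with elements `mu_A`, `mu_B`
#'   (mean logit sensitivity/specificity), `se_mu_A`, `se_mu_B`,
#'   `sigma2_A`, `sigma2_B`, `sigma_AB` (between-study (co)variances),
#'   `vcov_mu` (2x2 covariance of the mean estimates), `logLik`,
#'   `converged`, `boundary` (TRUE when a variance component was truncated
#'   at zero), `k`, `level`, and the stage-one `data`.
#' @export
fit_bivariate <- function(tables, level = 0.95) {
  need <- c("study_id", "TP", "FN", "FP", "TN")
  if (!all(need %in% names(tables))) {
    ipd_abort("tables must contain study_id, TP, FN, FP, TN", "ipddta_schema_error")
  }
  usable <- (tables$TP + tables$FN) > 0 & (tables$FP + tables$TN) > 0
  tables <- tables[usable, , drop = FALSE]
  k <- nrow(tables)
  if (k < 2) {
    ipd_abort("bivariate meta-analysis requires at least 2 usable studies",
              "ipddta_insufficient_data_error")
  }
  if (k < 4) {
    ipd_warn(sprintf("only %d studies: between-study covariance estimates will be unstable", k),
             "ipddta_few_studies_warning")
  }

  cc <- ifelse(tables$TP == 0 | tables$FN == 0 | tables$FP == 0 | tables$TN == 0,
               0.5, 0)
  tp <- tables$TP + cc; fn <- tables$FN + cc
  fp <- tables$FP + cc; tn <- tables$TN + cc
  stage1 <- data.frame(
    study_id = rep(tables$study_id, 2),
    outcome = rep(c("logit_sens", "logit_spec"), each = k),
    yi = c(log(tp / fn), log(tn / fp)),
    vi = c(1 / tp + 1 / fn, 1 / tn + 1 / fp))

  fit <- tryCatch(
    metafor::rma.mv(yi, vi, mods = ~ outcome - 1,
                    random = ~ outcome | study_id, struct = "UN",
                    data = stage1, method = "REML",
                    control = list(rel.tol = 1e-8, iter.max = 200)),
    error = function(e) {
      ipd_abort(sprintf("bivariate REML fit did not converge: %s",
                        conditionMessage(e)), "ipddta_convergence_error")
    })

  mu <- coef(fit)
  tau2 <- fit$tau2               # c(logit_sens, logit_spec)
  rho <- fit$rho
  if (is.na(rho)) rho <- 0
  boundary <- any(tau2 < 1e-8)
  sigma_AB <- rho * sqrt(tau2[1] * tau2[2])

  structure(list(
    mu_A = unname(mu[1]), mu_B = unname(mu[2]),
    se_mu_A = fit$se[1], se_mu_B = fit$se[2],
    sigma2_A = tau2[1], sigma2_B = tau2[2], sigma_AB = sigma_AB,
    rho = rho, vcov_mu = unname(vcov(fit)),
    logLik = as.numeric(stats::logLik(fit)), converged = TRUE,
    boundary = boundary, k = k, level = level, data = stage1),
    class = "bivariate_fit")
}

#' @export
print.bivariate_fit <- function(x, ...) {
  cat(sprintf("Bivariate random-effects fit (REML, %d studies)\n", x$k))
  cat(sprintf("  mean logit sensitivity  mu_A = %.4f (SE %.4f) -> Se = %.3f\n",
              x$mu_A, x$se_mu_A, plogis(x$mu_A)))
  cat(sprintf("  mean logit specificity  mu_B = %.4f (SE %.4f) -> Sp = %.3f\n",
              x$mu_B, x$se_mu_B, plogis(x$mu_B)))
  cat(sprintf("  between-study: var_A = %.4f, var_B = %.4f, cov_AB = %.4f (rho = %.3f)\n",
              x$sigma2_A, x$sigma2_B, x$sigma_AB, x$rho))
  if (x$boundary) cat("  note: a variance component was estimated at the boundary (0)\n")
  invisible(x)
}

#' Re-parameterize a bivariate fit as an HSROC model
#'
#' The bivariate model of (logit Se, logit Sp) without covariates is
#' mathematically equivalent to the hierarchical summary ROC (HSROC) model
#' with accuracy parameter Lambda, threshold parameter Theta and shape
#' parameter beta. With `s_A`, `s_B` the between-study SDs of logit
#' sensitivity and logit specificity:
#' \deqn{\beta = \log(s_B/s_A)}
#' \deqn{\Lambda = (s_B/s_A)^{1/2}\mu_A + (s_A/s_B)^{1/2}\mu_B}
#' \deqn{\Theta = \tfrac12\left[(s_B/s_A)^{1/2}\mu_A - (s_A/s_B)^{1/2}\mu_B\right]}
#' \deqn{\sigma^2_\theta = \tfrac12(s_A s_B - \sigma_{AB}), \quad
#'       \sigma^2_\alpha = 2(s_A s_B + \sigma_{AB})}
#' `beta = 0` (a symmetric summary ROC) holds exactly when the two
#' between-study variances are equal.
#'
#' @param b A `bivariate_fit` or a list with `mu_A`, `mu_B`, `sigma2_A`,
#'   `sigma2_B`, `sigma_AB`.
#' @return An object of class `hsroc_params`: list with `Lambda`, `Theta`,
#'   `beta`, `sigma2_alpha`, `sigma2_theta`.
#' @seealso [hsroc_to_bivariate()] for the exact inverse, [sroc_curve()].
#' @export
bivariate_to_hsroc <- function(b) {
  if (!all(c("mu_A", "mu_B", "sigma2_A", "sigma2_B", "sigma_AB") %in% names(b))) {
    ipd_abort("need mu_A, mu_B, sigma2_A, sigma2_B, sigma_AB", "ipddta_schema_error")
  }
  if (b$sigma2_A <= 0 || b$sigma2_B <= 0) {
    ipd_abort(paste("degenerate conversion: a between-study variance is zero;",
                    "in the homogeneity limit use beta = 0 with Lambda = mu_A + mu_B"),
              "ipddta_degenerate_error")
  }
  sA <- sqrt(b$sigma2_A); sB <- sqrt(b$sigma2_B)
  r <- sqrt(sB / sA)
  structure(list(
    Lambda = r * b$mu_A + b$mu_B / r,
    Theta = 0.5 * (r * b$mu_A - b$mu_B / r),
    beta = log(sB / sA),
    sigma2_alpha = 2 * (sA * sB + b$sigma_AB),
    sigma2_theta = 0.5 * (sA * sB - b$sigma_AB)),
    class = "hsroc_params")
}

#' Invert the HSROC re-parameterization
#'
#' Exact algebraic inverse of [bivariate_to_hsroc()].
#'
#' @param h An `hsroc_params` object (or compatible list).
#' @return A list with `mu_A`, `mu_B`, `sigma2_A`, `sigma2_B`, `sigma_AB`.
#' @export
hsroc_to_bivariate <- function(h) {
  b <- exp(h$beta / 2)
  P <- h$sigma2_theta + h$sigma2_alpha / 4     # s_A * s_B
  C <- h$sigma2_alpha / 4 - h$sigma2_theta     # sigma_AB
  list(mu_A = (h$Lambda / 2 + h$Theta) / b,
       mu_B = b * (h$Lambda / 2 - h$Theta),
       sigma2_A = P / exp(h$beta),
       sigma2_B = P * exp(h$beta),
       sigma_AB = C)
}

#' @export
print.hsroc_params <- function(x, ...) {
  cat("HSROC parameters\n")
  cat(sprintf("  Lambda (accuracy)  = %.4f\n", x$Lambda))
  cat(sprintf("  Theta  (threshold) = %.4f\n", x$Theta))
  cat(sprintf("  beta   (shape)     = %.4f\n", x$beta))
  cat(sprintf("  var(accuracy)  sigma2_alpha = %.4f\n", x$sigma2_alpha))
  cat(sprintf("  var(threshold) sigma2_theta = %.4f\n", x$sigma2_theta))
  invisible(x)
}

#' Summary ROC curve from HSROC parameters
#'
#' Traces the summary ROC curve
#' \deqn{\mathrm{logit}(TPR) = \Lambda e^{-\beta/2} + e^{-\beta}\,\mathrm{logit}(FPR)}
#' over a grid of false-positive rates. When `beta = 0` the curve is
#' symmetric: the difference logit(TPR) - logit(FPR) is constant and equals
#' Lambda (the log diagnostic odds ratio is constant along the curve). The
#' curve passes exactly through the summary operating point of the source
#' bivariate fit.
#'
#' @param h An `hsroc_params` object.
#' @param fpr_grid Optional vector of FPR values in (0,1); default is an
#'   equally spaced grid on `fpr_range`.
#' @param fpr_range Range to cover when `fpr_grid` is not given; typically
#'   the observed per-study FPR range to avoid extrapolation, or `c(0,1)`
#'   for the full curve (endpoints are pulled in by half a grid step).
#' @param n_grid Number of grid points (default 201).
#' @return Data frame with `fpr` and `tpr`, ordered by `fpr`.
#' @export
sroc_curve <- function(h, fpr_grid = NULL, fpr_range = c(0, 1), n_grid = 201) {
  if (is.null(fpr_grid)) {
    lo <- max(fpr_range[1], 1e-3); hi <- min(fpr_range[2], 1 - 1e-3)
    fpr_grid <- seq(lo, hi, length.out = n_grid)
  }
  if (any(fpr_grid <= 0 | fpr_grid >= 1)) {
    ipd_abort("fpr_grid values must lie strictly inside (0, 1)", "ipddta_domain_error")
  }
  tpr <- plogis(h$Lambda * exp(-h$beta / 2) + exp(-h$beta) * qlogis(fpr_grid))
  data.frame(fpr = fpr_grid, tpr = tpr)
}

#' Summary operating point with confidence region
#'
#' The summary sensitivity and specificity are the inverse logits of the
#' bivariate means. The joint confidence region for the mean pair is an
#' ellipse on the logit plane based on the estimated covariance of the
#' means; because the between-study covariance is itself estimated from a
#' small number of studies, the ellipse radius uses the small-sample
#' Hotelling-type quantile `2(k-1)/(k-2) F(level; 2, k-2)` rather than the
#' asymptotic chi-square quantile. The ellipse is mapped pointwise to ROC
#' coordinates (FPR = 1 - specificity, TPR = sensitivity).
#'
#' @param b A `bivariate_fit`.
#' @param level Confidence level; `0` degenerates the region to the point.
#' @param n_points Number of points on the ellipse boundary.
#' @return A list of class `summary_point`: `sensitivity`, `specificity`,
#'   `fpr`, `tpr`, `level`, and `region` (data frame of the boundary in
#'   both logit and ROC coordinates).
#' @export
summary_point <- function(b, level = 0.95, n_points = 181) {
  if (is.null(b$vcov_mu)) {
    ipd_abort("parameter covariance unavailable; refit with fit_bivariate()",
              "ipddta_missing_covariance_error")
  }
  if (b$k <= 2) {
    ipd_abort("confidence region requires more than 2 studies", "ipddta_insufficient_data_error")
  }
  r2 <- 2 * (b$k - 1) / (b$k - 2) * qf(level, 2, b$k - 2)
  ang <- seq(0, 2 * pi, length.out = n_points)
  circ <- cbind(cos(ang), sin(ang)) * sqrt(r2)
  pts <- circ %*% chol(b$vcov_mu)
  logit_sens <- b$mu_A + pts[, 1]
  logit_spec <- b$mu_B + pts[, 2]
  region <- data.frame(logit_sens = logit_sens, logit_spec = logit_spec,
                       fpr = plogis(-logit_spec), tpr = plogis(logit_sens))
  structure(list(sensitivity = plogis(b$mu_A), specificity = plogis(b$mu_B),
                 fpr = plogis(-b$mu_B), tpr = plogis(b$mu_A),
                 level = level, region = region),
            class = "summary_point")
}

#' Combined parameter table for export
#'
#' One tidy table holding both parameter sets of the summary meta-analysis:
#' the bivariate means and (co)variances and the equivalent HSROC
#' parameters.
#'
#' @param b A `bivariate_fit`.
#' @return Data frame with columns `model`, `parameter`, `estimate`, `se`
#'   (standard errors are available for the bivariate means only).
#' @export
model_parameter_table <- function(b) {
  h <- tryCatch(bivariate_to_hsroc(b), error = function(e) NULL)
  out <- data.frame(
    model = "bivariate",
    parameter = c("mu_A (mean logit Se)", "mu_B (mean logit Sp)",
                  "sigma2_A", "sigma2_B", "sigma_AB"),
    estimate = c(b$mu_A, b$mu_B, b$sigma2_A, b$sigma2_B, b$sigma_AB),
    se = c(b$se_mu_A, b$se_mu_B, NA, NA, NA))
  if (!is.null(h)) {
    out <- rbind(out, data.frame(
      model = "hsroc",
      parameter = c("Lambda", "Theta", "beta", "sigma2_alpha", "sigma2_theta"),
      estimate = c(h$Lambda, h$Theta, h$beta, h$sigma2_alpha, h$sigma2_theta),
      se = NA))
  }
  out
}
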