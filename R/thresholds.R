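#' Specify how continuous test results are dichotomized
#'
#' Three modes are supported, mirroring common practice in IPD re-analysis
#' of a continuous index test:
#'
#' * `"per_study"` -- one threshold per study, supplied via `values`
#'   (a named numeric vector, names = study ids); studies without a
#'   user-supplied value default to the median of all test results pooled
#'   across studies.
#' * `"optimal_youden"` -- the per-study cutpoint maximizing Youden's
#'   J = Se + Sp - 1 (see [youden_threshold()]). Note that optimizing the
#'   threshold within each primary study yields optimistically biased
#'   accuracy estimates; a caution is signalled on resolution.
#' * `"common_predefined"` -- a single predefined threshold (`common`)
#'   applied to every study.
#'
#' Throughout the package a patient is test-positive when
#' `test_result >= threshold` (higher values indicate disease); set
#' `invert = TRUE` for markers where lower values indicate disease
#' (the test results are negated internally).
#'
#' @param mode One of `"per_study"`, `"optimal_youden"`,
#'   `"common_predefined"`.
#' @param values Named numeric vector of per-study thresholds
#'   (mode `"per_study"` only; may cover a subset of studies).
#' @param common Single numeric threshold (mode `"common_predefined"`).
#' @param invert Logical; reverse the positivity direction.
#' @return A `threshold_spec` object; pass to [resolve_thresholds()].
#' @export
threshold_spec <- function(mode = c("per_study", "optimal_youden", "common_predefined"),
                           values = NULL, common = NULL, invert = FALSE) {
  mode <- match.arg(mode)
  if (mode == "common_predefined") {
    if (is.null(common) || length(common) != 1 || !is.finite(common)) {
      ipd_abort("mode 'common_predefined' requires a single finite 'common' threshold",
                "ipddta_validation_error")
    }
  }
  if (!is.null(values)) {
    if (is.null(names(values)) || any(!is.finite(values))) {
      ipd_abort("'values' must be a named vector of finite per-study thresholds",
                "ipddta_validation_error")
    }
  }
  structure(list(mode = mode, values = values, common = common,
                 invert = isTRUE(invert), resolved = NULL),
            class = "threshold_spec")
}

#' Resolve a threshold specification against a dataset
#'
#' Fills in one finite threshold per analyzable study according to the
#' spec's mode. In `"per_study"` mode, studies without a user value default
#' to the pooled median of all test results. In `"optimal_youden"` mode a
#' caution is signalled because per-study optimal thresholds can bias
#' summary accuracy upward; a caution is also signalled whenever resolved
#' thresholds differ across studies, since study-specific thresholds
#' complicate clinical interpretation.
#'
#' @param data An `ipd_dataset`.
#' @param spec A [threshold_spec()].
#' @return The spec with `$resolved` set: a named numeric vector of
#'   thresholds keyed by study id.
#' @export
resolve_thresholds <- function(data, spec) {
  stopifnot(inherits(spec, "threshold_spec"))
  ids <- analyzable_studies(data)
  if (!length(ids)) ipd_abort("no analyzable studies", "ipddta_empty_error")
  sgn <- if (spec$invert) -1 else 1
  resolved <- switch(spec$mode,
    common_predefined = setNames(rep(spec$common, length(ids)), ids),
    per_study = {
      pooled_median <- median(data$test_result, na.rm = TRUE)
      out <- setNames(rep(pooled_median, length(ids)), ids)
      user <- spec$values[names(spec$values) %in% as.character(ids)]
      out[names(user)] <- user
      out
    },
    optimal_youden = {
      ipd_caution(paste("optimal (Youden) thresholds are study-specific and may lead to",
                        "biased summary accuracy estimates; intended for exploration",
                        "and sensitivity analysis only"),
                  "ipddta_optimal_threshold_caution")
      # search on the positivity scale, report on the original scale
      setNames(vapply(ids, function(i) {
        v <- test_by_class(data, i)
        sgn * youden_threshold(sgn * v$diseased, sgn * v$nondiseased)$threshold
      }, numeric(1)), ids)
    })
  if (spec$mode != "optimal_youden" &&
      length(unique(resolved)) > 1) {
    ipd_caution("per-study thresholds differ across studies; summary estimates mix positivity definitions",
                "ipddta_mixed_threshold_caution")
  }
  spec$resolved <- resolved
  spec
}

#' Youden-optimal positivity threshold
#'
#' Exhaustive search for the cutpoint maximizing Youden's index
#' J = sensitivity + specificity - 1, with positivity defined as
#' `value >= threshold`. Candidate cutpoints are the midpoints between
#' consecutive distinct pooled values, plus `-Inf` and `+Inf` sentinels
#' (call everyone positive / everyone negative). Ties in J are broken by
#' the smallest threshold, which makes the result deterministic.
#'
#' @param diseased Numeric vector of test values in the diseased group.
#' @param nondiseased Numeric vector in the nondiseased group.
#' @return A list with `threshold` and `youden_j`.
#' @export
youden_threshold <- function(diseased, nondiseased) {
  diseased <- diseased[!is.na(diseased)]
  nondiseased <- nondiseased[!is.na(nondiseased)]
  if (!length(diseased) || !length(nondiseased)) {
    ipd_abort("both the diseased and nondiseased group must be non-empty to define a threshold",
              "ipddta_undefined_error")
  }
  v <- sort(unique(c(diseased, nondiseased)))
  cand <- c(-Inf, if (length(v) > 1) (v[-1] + v[-length(v)]) / 2, Inf)
  best_t <- NA_real_; best_j <- -Inf
  for (t in cand) {
    j <- mean(diseased >= t) + mean(nondiseased < t) - 1
    if (j > best_j + 1e-12) { best_j <- j; best_t <- t }
  }
  list(threshold = best_t, youden_j = best_j)
}
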