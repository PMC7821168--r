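#' Configuration for the synthetic IPD generator
#'
#' Defines a hypothetical multi-study diagnostic-accuracy dataset: a number
#' of primary studies, each contributing patients with a continuous
#' index-test value, a binary reference-standard status, one continuous and
#' one categorical patient-level covariate. The generative family is
#' binormal with a covariate shift: within study *i*, nondiseased test
#' values are `Normal(mu0_i + gamma * covariate, sd0^2)` and diseased
#' values are shifted by a study-specific disease effect
#' `Delta_i ~ Normal(effect_mean, effect_sd^2)` (the between-study
#' heterogeneity). Defaults describe 15 studies of moderate size with a
#' clearly informative test (standardized shift about 1.5, pooled AUC
#' around 0.85) and no missing values.
#'
#' @param n_studies Number of primary studies (default 15).
#' @param size_range Per-study sample-size range, drawn uniformly
#'   (default 80--150).
#' @param prevalence_range Per-study disease prevalence range (default
#'   0.25--0.50).
#' @param nondiseased_mean_range Range of the per-study nondiseased test
#'   mean `mu0_i` (default 8--12, arbitrary assay units).
#' @param nondiseased_sd,diseased_sd Within-group SDs of the test
#'   (default 2 and 2).
#' @param effect_mean Mean disease shift across studies (default 3).
#' @param effect_sd Between-study SD of the disease shift (default 0.75).
#' @param covariate_effect Slope `gamma` of the continuous covariate on the
#'   test result (default 0.05 per unit; both disease groups share it).
#' @param cont_covariate List `name`, `mean`, `sd` for the continuous
#'   covariate (default age ~ Normal(55, 10^2)).
#' @param cat_covariate List `name`, `levels`, `probs` for the categorical
#'   covariate (default sex, F/M at 50/50, no effect on the test).
#' @param missing_rates Named numeric vector of missingness proportions per
#'   output column (default none, matching a complete dataset).
#' @param seed Integer seed fixing the full output.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_studies = 15,
                         size_range = c(80, 150),
                         prevalence_range = c(0.25, 0.5),
                         nondiseased_mean_range = c(8, 12),
                         nondiseased_sd = 2, diseased_sd = 2,
                         effect_mean = 3, effect_sd = 0.75,
                         covariate_effect = 0.05,
                         cont_covariate = list(name = "age", mean = 55, sd = 10),
                         cat_covariate = list(name = "sex",
                                              levels = c("F", "M"),
                                              probs = c(0.5, 0.5)),
                         missing_rates = NULL,
                         seed = 20200909) {
  chk <- function(cond, field) {
    if (!cond) ipd_abort(sprintf("invalid synth_config field: %s", field),
                         "ipddta_validation_error")
  }
  chk(n_studies >= 1, "n_studies")
  chk(length(size_range) == 2 && all(size_range >= 2), "size_range")
  chk(all(prevalence_range > 0 & prevalence_range < 1), "prevalence_range")
  chk(nondiseased_sd > 0, "nondiseased_sd")
  chk(diseased_sd > 0, "diseased_sd")
  chk(effect_sd >= 0, "effect_sd")
  chk(cont_covariate$sd > 0, "cont_covariate$sd")
  chk(abs(sum(cat_covariate$probs) - 1) < 1e-8, "cat_covariate$probs")
  chk(is.null(missing_rates) ||
        (!is.null(names(missing_rates)) && all(missing_rates >= 0 & missing_rates < 1)),
      "missing_rates")
  chk(is.numeric(seed) && length(seed) == 1, "seed")
  structure(list(n_studies = n_studies, size_range = size_range,
                 prevalence_range = prevalence_range,
                 nondiseased_mean_range = nondiseased_mean_range,
                 nondiseased_sd = nondiseased_sd, diseased_sd = diseased_sd,
                 effect_mean = effect_mean, effect_sd = effect_sd,
                 covariate_effect = covariate_effect,
                 cont_covariate = cont_covariate, cat_covariate = cat_covariate,
                 missing_rates = missing_rates, seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a hypothetical pooled IPD dataset
#'
#' Draws a multi-study dataset from a [synth_config()]. Each study uses its
#' own deterministic random substream derived from the master seed, so
#' increasing `n_studies` reproduces the earlier studies unchanged. The
#' output passes the [as_ipd_dataset()] validation.
#'
#' @param config A `synth_config` (default `synth_config()`).
#' @return An `ipd_dataset` with the configuration attached as attribute
#'   `synth_config`.
#' @export
generate_ipd <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  study_seeds <- sample.int(.Machine$integer.max - 1L, config$n_studies)

  per_study <- lapply(seq_len(config$n_studies), function(i) {
    set.seed(study_seeds[i])
    n <- round(runif(1, config$size_range[1], config$size_range[2]))
    prev <- runif(1, config$prevalence_range[1], config$prevalence_range[2])
    mu0 <- runif(1, config$nondiseased_mean_range[1], config$nondiseased_mean_range[2])
    delta <- rnorm(1, config$effect_mean, config$effect_sd)

    disease <- rbinom(n, 1, prev)
    cont <- rnorm(n, config$cont_covariate$mean, config$cont_covariate$sd)
    cat_ <- sample(config$cat_covariate$levels, n, replace = TRUE,
                   prob = config$cat_covariate$probs)
    sdv <- ifelse(disease == 1, config$diseased_sd, config$nondiseased_sd)
    y <- rnorm(n, mu0 + config$covariate_effect * cont + delta * disease, sdv)

    out <- data.frame(Study = sprintf("Study %02d", i),
                      `test.results` = y, disease = disease,
                      check.names = FALSE, stringsAsFactors = FALSE)
    out[[config$cont_covariate$name]] <- cont
    out[[config$cat_covariate$name]] <- cat_
    out
  })
  df <- do.call(rbind, per_study)

  if (!is.null(config$missing_rates)) {
    set.seed(config$seed + 1L)
    for (nm in names(config$missing_rates)) {
      if (!nm %in% names(df)) {
        ipd_abort(sprintf("missing_rates names an unknown column: %s", nm),
                  "ipddta_validation_error")
      }
      df[[nm]][runif(nrow(df)) < config$missing_rates[[nm]]] <- NA
    }
  }
  out <- as_ipd_dataset(df)
  attr(out, "synth_config") <- config
  out
}

#' Simulate a dichotomized meta-analysis with known bivariate truth
#'
#' Known-truth generator for parameter-recovery studies of the bivariate
#' model: per study, true (logit Se, logit Sp) are drawn from a bivariate
#' normal with means `mu` and covariance built from `sds` and `rho`;
#' diseased and nondiseased group sizes follow a balanced design (the
#' diseased count is binomial with probability `prevalence`), and the 2x2
#' cell counts are binomial at the study-specific Se/Sp.
#'
#' @param k Number of studies.
#' @param n Patients per study.
#' @param mu Length-2 vector: mean logit sensitivity, mean logit specificity.
#' @param sds Length-2 vector of between-study SDs.
#' @param rho Between-study correlation.
#' @param prevalence Probability a patient is diseased (default 0.5).
#' @return Data frame of per-study 2x2 tables (`study_id`, `TP`, `FN`,
#'   `FP`, `TN`) suitable for [fit_bivariate()].
#' @export
simulate_dichotomous_meta <- function(k, n, mu, sds, rho, prevalence = 0.5) {
  Sigma <- diag(sds) %*% matrix(c(1, rho, rho, 1), 2) %*% diag(sds)
  re <- rbvnorm(k, mu, Sigma)
  tabs <- t(vapply(seq_len(k), function(i) {
    nd <- rbinom(1, n, prevalence); nn <- n - nd
    tp <- rbinom(1, nd, plogis(re[i, 1]))
    tn <- rbinom(1, nn, plogis(re[i, 2]))
    c(TP = tp, FN = nd - tp, FP = nn - tn, TN = tn)
  }, numeric(4)))
  data.frame(study_id = seq_len(k), tabs)
}
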