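# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force pair counting for the AUC,
# exhaustive evaluation for the Youden search, closed-form inverse-variance
# algebra for pooling.

# AUC as the explicit proportion of concordant (diseased, nondiseased)
# pairs, ties counted one half.
brute_auc <- function(diseased, nondiseased) {
  cmp <- outer(diseased, nondiseased, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Evaluate Youden's J at every candidate cutpoint (midpoints between
# consecutive distinct pooled values plus sentinels); return the maximum J
# and the smallest threshold attaining it.
brute_youden <- function(diseased, nondiseased) {
  v <- sort(unique(c(diseased, nondiseased)))
  cand <- c(-Inf, if (length(v) > 1) (head(v, -1) + tail(v, -1)) / 2, Inf)
  j <- vapply(cand, function(t) {
    mean(diseased >= t) + mean(nondiseased < t) - 1
  }, numeric(1))
  jmax <- max(j)
  list(threshold = min(cand[j >= jmax - 1e-12]), youden_j = jmax)
}

# Closed-form fixed-effect and DerSimonian-Laird pooling.
brute_pool <- function(yi, sei) {
  w <- 1 / sei^2
  fixed <- sum(w * yi) / sum(w)
  q <- sum(w * (yi - fixed)^2)
  k <- length(yi)
  tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (sei^2 + tau2)
  list(fixed = fixed, fixed_se = sqrt(1 / sum(w)),
       random = sum(wr * yi) / sum(wr), random_se = sqrt(1 / sum(wr)),
       q = q, tau2 = tau2)
}

# Build a validated dataset from parallel vectors; .types overrides the
# automatic covariate typing (few-distinct-value numeric columns default to
# categorical).
make_ipd <- function(study, test, disease, ..., .types = NULL) {
  df <- data.frame(Study = study, `test.results` = test, disease = disease,
                   check.names = FALSE, stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  as_ipd_dataset(df, covariate_types = .types)
}

# Write a small IPD table to a temporary delimited file.
write_ipd_tmp <- function(df, sep = ",") {
  path <- tempfile(fileext = ".csv")
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  path
}

# Two-group dataset with known structure for quick pipeline tests.
toy_two_study <- function() {
  make_ipd(study = rep(c("A", "B"), each = 8),
           test = c(1, 2, 3, 4, 5, 6, 7, 8, 2, 3, 4, 5, 6, 7, 8, 9),
           disease = rep(c(0, 0, 0, 0, 1, 1, 1, 1), 2))
}
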