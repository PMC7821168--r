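# Independent step-by-step oracle for the placement-value estimator with an
# intercept-only location model: explicit mean, n-p residual scale, and a
# manual right-continuous ECDF.
oracle_aroc_intercept_only <- function(y_nondiseased, y_diseased) {
  b0 <- mean(y_nondiseased)
  res <- y_nondiseased - b0
  sigma <- sqrt(sum(res^2) / (length(res) - 1))
  e <- res / sigma
  Fhat <- function(x) mean(e <= x)
  u <- vapply((y_diseased - b0) / sigma, function(x) 1 - Fhat(x), numeric(1))
  list(b0 = b0, sigma = sigma, u = u, aauc = 1 - mean(u))
}

test_that("worked intercept-only example reproduces the stated conventions exactly", {
  d <- make_ipd(rep("A", 4), c(1, 2, 3, 2.5), c(0, 0, 0, 1))
  fit <- fit_aroc(d, covariate = NULL)
  expect_equal(unname(fit$coefficients), 2)
  expect_equal(fit$sigma_hat, 1)
  expect_equal(fit$placement$u, 1 / 3)
  expect_equal(fit$aauc, 2 / 3)

  o <- oracle_aroc_intercept_only(c(1, 2, 3), 2.5)
  expect_equal(fit$placement$u, o$u)
  expect_equal(fit$aauc, o$aauc)

  # larger random instance against the same oracle
  set.seed(81)
  yn <- rnorm(40); yd <- rnorm(25, 1)
  d2 <- make_ipd(rep("A", 65), c(yn, yd), rep(c(0, 1), c(40, 25)))
  f2 <- fit_aroc(d2, covariate = NULL)
  o2 <- oracle_aroc_intercept_only(yn, yd)
  expect_equal(f2$placement$u, o2$u, tolerance = 1e-12)
  expect_equal(f2$aauc, o2$aauc, tolerance = 1e-12)
})

test_that("covariate distribution summaries: balance, normalization, degenerate covariate", {
  d <- make_ipd(rep("A", 8), 1:8, rep(c(0, 1), 4),
                sex = rep(c("M", "M", "F", "F"), 2))
  cd <- covariate_distributions(d, "sex")
  expect_equal(cd$type, "categorical")
  expect_true(all(abs(tapply(cd$summary$pct,
                             interaction(cd$summary$study_id, cd$summary$group),
                             sum) - 100) < 1e-8))
  expect_true(all(cd$summary$pct == 50))

  set.seed(91)
  dc <- make_ipd(rep("A", 60), rnorm(60), rbinom(60, 1, 0.5),
                 age = rnorm(60, 50, 8))
  cc <- covariate_distributions(dc, "age")
  expect_equal(cc$type, "continuous")
  for (key in split(cc$summary, interaction(cc$summary$study_id, cc$summary$group, drop = TRUE))) {
    area <- sum(diff(key$x) * (head(key$density, -1) + tail(key$density, -1)) / 2)
    expect_equal(area, 1, tolerance = 1e-3)
  }

  dconst <- make_ipd(rep("A", 6), 1:6, rep(c(0, 1), 3), site = rep(5, 6),
                     .types = c(site = "continuous"))
  expect_warning(cdc <- covariate_distributions(dconst, "site"),
                 class = "ipddta_degenerate_covariate_warning")
  expect_equal(cdc$type, "categorical")
  expect_true(all(cdc$summary$pct == 100))

  expect_error(covariate_distributions(d, "nope"), class = "ipddta_lookup_error")
})

test_that("per-study regressions: exact line, skips, closed-form oracle", {
  d <- make_ipd(rep("A", 3), c(1, 3, 5), c(0, 1, 0), x = c(0, 1, 2),
                .types = c(x = "continuous"))
  f <- suppressWarnings(per_study_regressions(d, "x"))  # exact fit warns in summary.lm
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r_squared, 1)

  dd <- suppressWarnings(make_ipd(c(rep("A", 5), rep("B", 5)),
                                  c(rnorm(5), rnorm(5)),
                                  c(0, 1, 0, 1, 0, 1, 0, 1, 0, 1),
                                  x = c(rnorm(5), rep(2, 5)),
                                  .types = c(x = "continuous")))
  expect_warning(fs <- per_study_regressions(dd, "x"),
                 class = "ipddta_regression_skipped_warning")
  expect_equal(fs$study_id, 1L)

  # OLS equals the normal-equations solution
  set.seed(101)
  x <- rnorm(50); y <- 2 + 0.7 * x + rnorm(50, sd = 0.5)
  d3 <- make_ipd(rep("A", 50), y, rbinom(50, 1, 0.5), x = x)
  f3 <- per_study_regressions(d3, "x")
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(c(f3$intercept, f3$slope), as.numeric(beta), tolerance = 1e-10)

  d4 <- make_ipd(rep("A", 4), 1:4, c(0, 1, 0, 1), g = c("a", "b", "a", "b"))
  expect_error(per_study_regressions(d4, "g"), class = "ipddta_type_error")
})

test_that("placement values are uniform under the null and AAUC is near one half", {
  set.seed(111)
  n <- 2000
  x <- rnorm(n, 50, 10)
  dis <- rbinom(n, 1, 0.4)
  y <- 1 + 0.5 * x + rnorm(n)          # no disease effect at all
  d <- make_ipd(rep(c("A", "B"), n / 2), y, dis, age = x)
  fit <- fit_aroc(d, "age")
  expect_lt(abs(fit$aauc - 0.5), 0.03)
  ks <- suppressWarnings(stats::ks.test(fit$placement$u, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("with no covariate effect the adjusted ROC reduces to the pooled empirical ROC", {
  set.seed(121)
  n <- 2000
  x <- rnorm(n, 50, 10)
  dis <- rbinom(n, 1, 0.4)
  y <- 2 + 0 * x + 1.5 * dis + rnorm(n)   # covariate inert, disease shifts
  d <- make_ipd(rep(c("A", "B"), n / 2), y, dis, age = x)
  fit <- fit_aroc(d, "age")
  grid <- seq(0.01, 0.99, by = 0.01)
  adj <- aroc_curve(fit, grid)$aroc
  rp <- roc_points(y[dis == 1], y[dis == 0])
  emp <- stats::approxfun(rp$fpr, rp$tpr, method = "constant", f = 0,
                          ties = max, rule = 2)(grid)
  expect_lt(max(abs(adj - emp)), 0.03)
})

test_that("AAUC is invariant to affine transformations of the test scale", {
  set.seed(131)
  n <- 400
  x <- rnorm(n); dis <- rbinom(n, 1, 0.5)
  y <- 1 + 0.4 * x + 1.2 * dis + rnorm(n)
  d1 <- make_ipd(rep("A", n), y, dis, z = x)
  d2 <- make_ipd(rep("A", n), 3.7 * y - 11, dis, z = x)
  f1 <- fit_aroc(d1, "z"); f2 <- fit_aroc(d2, "z")
  expect_equal(f1$placement$u, f2$placement$u, tolerance = 1e-10)
  expect_equal(f1$aauc, f2$aauc, tolerance = 1e-10)
})

test_that("nondiseased regression recovers the generating slope", {
  set.seed(141)
  n <- 2000
  x <- rnorm(n)
  dis <- rbinom(n, 1, 0.5)
  y <- 1 + 0.5 * x + 1.5 * dis + rnorm(n)
  d <- make_ipd(rep("A", n), y, dis, z = x)
  fit <- fit_aroc(d, "z")
  expect_lt(abs(unname(fit$coefficients["z"]) - 0.5), 0.1)
})

test_that("adjusted curve contract: bounds, monotonicity, quadrature, categorical covariates", {
  set.seed(151)
  n <- 300
  x <- rnorm(n); dis <- rbinom(n, 1, 0.4)
  y <- 1 + 0.3 * x + dis + rnorm(n)
  sexv <- sample(c("F", "M"), n, replace = TRUE)
  d <- make_ipd(rep("A", n), y, dis, z = x, sex = sexv)

  for (cov in list("z", "sex", NULL)) {
    fit <- fit_aroc(d, cov)
    cur <- aroc_curve(fit)
    expect_equal(cur$aroc[cur$t == 0], 0)
    expect_equal(cur$aroc[cur$t == 1], 1)
    expect_true(all(diff(cur$aroc) >= 0))
    expect_true(all(fit$placement$u >= 0 & fit$placement$u <= 1))
    dense <- aroc_curve(fit, seq(0, 1, by = 1 / 4096))
    trap <- sum(diff(dense$t) * (head(dense$aroc, -1) + tail(dense$aroc, -1)) / 2)
    expect_lt(abs(trap - fit$aauc), 1 / fit$n_diseased)
  }

  v <- aroc_view(fit_aroc(d, "z"))
  expect_named(v, c("curve", "aauc", "summary"))
  expect_equal(v$summary$aauc, v$aauc)

  tiny <- make_ipd(rep("A", 4), c(1, 2, 3, 2.5), c(0, 0, 0, 1), z = c(1, 2, 3, 2))
  expect_error(fit_aroc(tiny, "z"), class = "ipddta_insufficient_data_error")
})
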