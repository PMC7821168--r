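test_that("Youden search: separation, no discrimination, tie-break, brute-force agreement", {
  r <- youden_threshold(c(3, 4, 5), c(1, 2))
  expect_equal(r$threshold, 2.5)
  expect_equal(r$youden_j, 1)

  # identical groups: no discrimination, J = 0 at the sentinel cutpoint
  r0 <- youden_threshold(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$youden_j, 0)
  expect_identical(r0$threshold, -Inf)

  expect_error(youden_threshold(numeric(0), c(1, 2)),
               class = "ipddta_undefined_error")

  set.seed(101)
  for (i in 1:50) {
    d <- sample(0:8, sample(3:12, 1), replace = TRUE)
    n <- sample(0:8, sample(3:12, 1), replace = TRUE)
    got <- youden_threshold(d, n)
    want <- brute_youden(d, n)
    expect_equal(got$youden_j, want$youden_j, tolerance = 1e-12)
    expect_equal(got$threshold, want$threshold)
  }
})

test_that("threshold resolution: pooled-median default, common value, optimal mode caution", {
  d <- make_ipd(c("A", "A", "A", "B", "B"), c(1, 2, 3, 4, 5),
                c(0, 1, 0, 0, 1))
  spec <- resolve_thresholds(d, threshold_spec("per_study"))
  expect_equal(unname(spec$resolved), c(3, 3))   # median of {1..5}

  spec_u <- suppressMessages(
    resolve_thresholds(d, threshold_spec("per_study", values = c(`2` = 4.5))))
  expect_equal(unname(spec_u$resolved), c(3, 4.5))

  spec_c <- resolve_thresholds(d, threshold_spec("common_predefined", common = 2.5))
  expect_equal(unname(spec_c$resolved), c(2.5, 2.5))

  expect_condition(resolve_thresholds(d, threshold_spec("optimal_youden")),
                   class = "ipddta_optimal_threshold_caution")
  spec_o <- suppressMessages(resolve_thresholds(d, threshold_spec("optimal_youden")))
  for (i in 1:2) {
    v <- ipddta:::test_by_class(d, i)
    expect_equal(unname(spec_o$resolved[as.character(i)]),
                 brute_youden(v$diseased, v$nondiseased)$threshold)
  }

  expect_error(threshold_spec("common_predefined", common = NA),
               class = "ipddta_validation_error")
  expect_error(threshold_spec("per_study", values = c(`1` = Inf)),
               class = "ipddta_validation_error")
})

test_that("2x2 tables: worked cells, degenerate thresholds, margins on simulated data", {
  d <- make_ipd(rep("A", 4), c(2, 4, 1, 3), c(1, 1, 0, 0))
  tab <- contingency_table(d, 1, 2.5)
  expect_equal(unlist(tab[c("TP", "FN", "FP", "TN")]),
               c(TP = 1, FN = 1, FP = 1, TN = 1))

  low <- contingency_table(d, 1, 0)   # everything positive
  expect_equal(low$FN + low$TN, 0)

  expect_error(contingency_table(d, 99, 2), class = "ipddta_lookup_error")

  set.seed(7)
  y <- rnorm(200); dis <- rbinom(200, 1, 0.35)
  if (!any(dis == 1)) dis[1] <- 1
  sim <- make_ipd(rep("S", 200), y, dis)
  for (thr in quantile(y, c(0.1, 0.5, 0.9))) {
    tt <- contingency_table(sim, 1, thr)
    expect_equal(tt$TP + tt$FN, sum(dis == 1))
    expect_equal(tt$FP + tt$TN, sum(dis == 0))
  }
})

test_that("accuracy panel: closed forms, continuity correction, transposition symmetry", {
  p <- accuracy_panel(list(TP = 90, FN = 10, FP = 20, TN = 80))
  expect_equal(p$sens, 0.90)
  expect_equal(p$spec, 0.80)
  expect_equal(p$lr_pos, 4.5)
  expect_equal(p$lr_neg, 0.125)
  expect_equal(p$dor, 36)
  expect_equal(p$ppv, 90 / 110)
  expect_equal(p$npv, 80 / 90)
  expect_false(p$continuity_corrected)
  # CI bounds bracket the estimates inside the parameter support
  expect_true(p$sens_low <= p$sens && p$sens <= p$sens_high)
  expect_true(p$dor_low <= p$dor && p$dor <= p$dor_high)
  expect_true(p$sens_low >= 0 && p$sens_high <= 1)

  # zero cells: proportions raw, ratios from the corrected table
  p0 <- accuracy_panel(list(TP = 0, FN = 10, FP = 0, TN = 10))
  expect_equal(p0$sens, 0)
  expect_equal(p0$spec, 1)
  expect_true(p0$continuity_corrected)
  expect_equal(p0$dor, (0.5 * 10.5) / (0.5 * 10.5))   # cells 0.5/10.5/0.5/10.5
  expect_equal(p0$lr_pos, (0.5 / 11) / (0.5 / 11))

  psym <- accuracy_panel(list(TP = 5, FN = 5, FP = 5, TN = 5))
  expect_equal(c(psym$sens, psym$spec, psym$ppv, psym$npv), rep(0.5, 4))
  expect_equal(psym$dor, 1)

  # transposing the table (TP<->TN, FP<->FN) swaps Se/Sp, maps LR+ -> 1/LR-,
  # and leaves the DOR unchanged
  a <- accuracy_panel(list(TP = 31, FN = 9, FP = 12, TN = 48))
  b <- accuracy_panel(list(TP = 48, FN = 12, FP = 9, TN = 31))
  expect_equal(b$sens, a$spec)
  expect_equal(b$spec, a$sens)
  expect_equal(b$lr_pos, 1 / a$lr_neg)
  expect_equal(b$dor, a$dor)

  expect_error(accuracy_panel(list(TP = 0, FN = 0, FP = 0, TN = 0)),
               class = "ipddta_empty_error")
})

test_that("empirical AUC: worked examples, tie symmetry, brute-force pairs, DeLong vs pROC", {
  expect_equal(empirical_auc(c(2, 4), c(1, 3))$auc, 0.75)
  expect_equal(empirical_auc(c(1, 2), c(1, 2))$auc, 0.5)
  expect_error(empirical_auc(numeric(0), 1:3), class = "ipddta_undefined_error")

  set.seed(11)
  d <- rnorm(50, 1); n <- rnorm(50)
  a <- empirical_auc(d, n)
  expect_equal(a$auc, brute_auc(d, n), tolerance = 1e-12)

  # DeLong SE cross-checked against the reference implementation in pROC
  r <- pROC::roc(cases = d, controls = n, direction = "<", quiet = TRUE)
  expect_equal(a$auc, as.numeric(pROC::auc(r)), tolerance = 1e-12)
  expect_equal(a$se^2, as.numeric(pROC::var(r)), tolerance = 1e-10)

  # with heavy ties too
  dt <- sample(1:4, 40, replace = TRUE); nt <- sample(1:4, 30, replace = TRUE)
  expect_equal(empirical_auc(dt, nt)$auc, brute_auc(dt, nt), tolerance = 1e-12)
})

test_that("AUC equals the trapezoidal area under the empirical ROC at all cutpoints", {
  set.seed(21)
  for (i in 1:10) {
    d <- sample(1:6, 25, replace = TRUE) + rnorm(25, sd = 0.01 * (i %% 2))
    n <- sample(1:6, 20, replace = TRUE) + rnorm(20, sd = 0.01 * (i %% 2))
    rp <- roc_points(d, n)
    trap <- sum(diff(rp$fpr) * (head(rp$tpr, -1) + tail(rp$tpr, -1)) / 2)
    expect_equal(empirical_auc(d, n)$auc, trap, tolerance = 1e-12)
  }
})

test_that("raising the threshold never raises sensitivity nor lowers specificity", {
  set.seed(31)
  y <- rnorm(120); dis <- rbinom(120, 1, 0.4)
  dd <- make_ipd(rep("A", 120), y, dis)
  thr <- sort(c(-Inf, quantile(y, seq(0.05, 0.95, by = 0.05)), Inf))
  res <- t(vapply(thr, function(t) {
    tt <- contingency_table(dd, 1, t)
    c(se = tt$TP / (tt$TP + tt$FN), sp = tt$TN / (tt$TN + tt$FP))
  }, numeric(2)))
  expect_true(all(diff(res[, "se"]) <= 1e-12))
  expect_true(all(diff(res[, "sp"]) >= -1e-12))
})

test_that("inverted positivity direction mirrors the standard analysis", {
  d <- make_ipd(rep("A", 6), c(1, 2, 3, 4, 5, 6), c(1, 1, 1, 0, 0, 0))
  spec <- suppressMessages(
    resolve_thresholds(d, threshold_spec("optimal_youden", invert = TRUE)))
  tab <- contingency_table(d, 1, spec$resolved[["1"]], invert = TRUE)
  expect_equal(tab$TP, 3)  # low values flag disease after inversion
  expect_equal(tab$TN, 3)
})
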