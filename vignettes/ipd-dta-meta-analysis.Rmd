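---
title: "Methods: IPD meta-analysis of diagnostic test accuracy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IPD meta-analysis of diagnostic test accuracy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical methods implemented in `ipddta`,
their assumptions, the tunable parameters and their defaults, the numerical
conventions the results depend on, and the design decisions taken where
several defensible options existed.

## The data model

The unit of analysis is the *pooled individual participant data* (IPD)
table: one row per patient, with a study label, a continuous index-test
value, a binary reference-standard disease status, and any number of
patient-level covariates. Study ids are assigned 1..K in order of first
appearance of each label; the assignment is therefore stable under row
re-sorting only if the first-appearance order of the labels is preserved.

Numeric covariate columns with at most 10 distinct observed values default
to categorical (override per column via `covariate_types`); non-numeric
columns are always categorical. The empty string and `"NA"` are recognized
as missing. Missing data are handled by *per-analysis complete cases*: a
record missing a covariate leaves only the analyses that use that
covariate. Studies with a single disease class are flagged and excluded
from per-study accuracy computations but never silently deleted.

## Dichotomizing a continuous test

A patient is test-positive when `test_result >= threshold` ("higher value
indicates disease"); a global `invert` flag negates the scale for markers
with the opposite orientation. The closed-on-the-positive-side convention
matters: patients sitting exactly on the threshold flip categories between
`>=` and `>`, so it is fixed and documented rather than left to chance.

Three threshold modes are supported. *Per study* uses user-supplied values
with the pooled median of all test results as the default; *common* applies
one predefined value everywhere; *Youden-optimal* maximizes
J = Se + Sp − 1 within each study by exhaustive search over candidate
cutpoints — the midpoints between consecutive distinct pooled values plus
−∞/+∞ sentinels — breaking ties toward the smallest threshold so the result
is deterministic. Optimizing the cutpoint inside each primary study makes
the resulting summary accuracy optimistically biased, so this mode signals
a caution and is intended for exploration and sensitivity analysis only;
mixed per-study thresholds trigger the same kind of caution because they
blur the clinical meaning of the summary estimate.

The per-study accuracy panel uses Clopper–Pearson exact intervals for the
four proportions (Se, Sp, PPV, NPV) and log-scale Wald intervals for the
ratio measures (LR+, LR−, DOR). When any 2×2 cell is zero, a 0.5 continuity
correction is applied to all four cells *for the ratio measures only*; the
proportions are reported from the raw cells. The per-study AUC is the
threshold-free empirical (Mann–Whitney) AUC of the continuous values, ties
weighted one half, with DeLong's standard error; in the degenerate case
(AUC exactly 0 or 1 — zero DeLong variance) a floor based on the
Hanley–McNeil variance at an AUC half a pair off the boundary is
substituted and the study is flagged.

## Bivariate summary model and the HSROC view

The summary meta-analysis is the standard two-stage normal approximation:
per study, observed logit sensitivity and logit specificity with
within-study variances `1/TP + 1/FN` and `1/TN + 1/FP` (0.5 added to all
four cells of any study containing a zero cell — only the affected
studies); across studies, a bivariate normal with means (μ_A, μ_B) and an
unstructured covariance, estimated by REML (`metafor::rma.mv`,
relative tolerance 1e-8, 200 iterations; boundary variance estimates are
truncated at zero and flagged). The approximation assumes the per-study
logits are roughly normal with known variances, which is adequate at the
study sizes the package targets (tens to hundreds of patients per group)
and increasingly poor for very small or near-degenerate tables.

The fit is re-expressed exactly in hierarchical summary ROC (HSROC) form:
with s_A, s_B the between-study SDs,

* β = log(s_B/s_A) (shape; 0 iff the two variances are equal),
* Λ = (s_B/s_A)^{1/2} μ_A + (s_A/s_B)^{1/2} μ_B (accuracy),
* Θ = [(s_B/s_A)^{1/2} μ_A − (s_A/s_B)^{1/2} μ_B]/2 (threshold),
* σ²_θ = (s_A s_B − σ_AB)/2, σ²_α = 2(s_A s_B + σ_AB).

The mapping has an exact algebraic inverse (`hsroc_to_bivariate`), verified
in the tests to machine precision, and degenerates when a between-study
variance is zero — in that homogeneity limit the symmetric curve with
Λ = μ_A + μ_B is the sensible substitute, and the converter says so in its
error. The summary ROC curve is
logit(TPR) = Λ e^{−β/2} + e^{−β} logit(FPR), clipped by default to the
observed per-study FPR range to avoid extrapolation (`full_range = TRUE`
overrides). Substituting logit(FPR) = −μ_B yields logit(TPR) = μ_A for any
β, so the curve passes exactly through the summary operating point; the
test suite asserts this identity at 1e-8.

**Confidence region.** The joint region for (μ_A, μ_B) is an ellipse on the
logit plane from the REML covariance of the means. Because that covariance
is itself estimated from few studies, the asymptotic chi-square radius
undercovers noticeably at K ≈ 15 (about 0.86 empirical coverage in our
design calibration); the package therefore uses the Hotelling-type radius
`2(K−1)/(K−2) · F(level; 2, K−2)`, which calibrated at ≈ 0.94 for a nominal
0.95 under the bivariate generative model. The region requires K > 2, and
`level = 0` collapses it to the point.

## AUC meta-analysis

Per-study empirical AUCs are pooled by inverse variance: the common-effect
estimate with weights 1/se², and DerSimonian–Laird random effects with
weights 1/(se² + τ²); Q, I² = max(0, (Q − (K−1))/Q) and τ² are reported and
both weight sets are normalized to sum to one. Pooling defaults to the raw
AUC scale (the convention of generic inverse-variance meta-analysis tools),
whose confidence limits can spill outside [0,1]; they are clipped with a
warning, and a logit-scale option with delta-method standard errors is
provided for bounded intervals. On the logit scale boundary AUCs enter
through their continuity-adjusted values. Random-effects intervals are
never narrower than fixed-effect intervals on the same data, and with equal
standard errors the fixed-effect estimate is the arithmetic mean — both are
asserted in tests.

## Covariate-adjusted ROC

The adjusted analysis asks how well the test separates diseased from
nondiseased *given* a patient-level covariate, removing the part of the
separation that merely reflects covariate imbalance. The estimator is the
frequentist semiparametric one: a linear location model for the test result
fitted in the pooled nondiseased sample (categorical covariates through
indicator coding; one covariate at a time), residual scale σ̂ with
denominator n − p, the right-continuous ECDF F̂ of the standardized
nondiseased residuals, placement values U = 1 − F̂((y − x'b)/σ̂) for the
diseased, AROC(t) = mean(U ≤ t) and AAUC = 1 − mean(U). These conventions
(right-continuous ECDF, n − p denominator) are stated because the worked
example in the tests depends on them digit for digit. A Bayesian
nonparametric variant exists in the literature; the frequentist estimator
was chosen as the supported method because it is closed-form, dependency
free, and directly testable against hand computation.

Two conventions deserve a note. First, the regression pools nondiseased
subjects across studies without study effects — the single-covariate
adjustment scope; a study-indicator extension is possible but off by
default, and this pooling is flagged as an interpretation. Second, a
diseased subject whose standardized residual exceeds every nondiseased one
has U = 0 exactly, so the empirical AROC can be positive arbitrarily close
to t = 0; the exported curve reports the limit value 0 at t = 0 and lets
that mass enter at the first positive grid point (default grid 0 to 1 in
steps of 0.005). The trapezoidal integral of the curve then agrees with
AAUC to within 1/n_D.

Model assumptions: location-shift dependence of the test on the covariate
with homoscedastic errors in the nondiseased group. Under the null (test
independent of disease given the covariate) placement values are uniform —
checked by simulation at n = 2000; with a slope of zero the adjusted curve
reduces to the pooled empirical ROC; and the AAUC is invariant to affine
rescaling of the test.

## Synthetic data: what it emulates and what it does not

`generate_ipd()` draws the hypothetical multi-study dataset used throughout
the tests: 15 primary studies of 80–150 patients, prevalence 0.25–0.50,
nondiseased test mean uniform on 8–12 arbitrary assay units with SD 2, a
study-specific disease shift Δ_i ~ N(3, 0.75²) (between-study
heterogeneity), a continuous covariate (age ~ N(55, 10²)) with a mild slope
of 0.05 units per year on the test, an inert balanced categorical covariate
(sex), and no missing values. The standardized shift of about 1.5 puts the
pooled AUC near 0.86 — a clearly informative but imperfect test, the
interesting regime for threshold and heterogeneity analyses. Missingness
can be injected per column for the complete-case tests. Each study draws
from its own seed-derived substream, so enlarging the meta-analysis leaves
earlier studies unchanged.

The generator is binormal with a linear covariate effect shared by both
groups. It does not emulate skewed or heavy-tailed assay distributions,
covariate-dependent variance, study-level confounding, verification bias,
or informative missingness — so green tests certify the estimators under a
correctly specified location-shift world, not robustness to those
violations. The frozen fixture `inst/extdata/ipd_synthetic.csv` is the
default generator output with test values rounded to 2 decimals (age to 1);
it is a synthetic stand-in, not a reproduction of any published dataset.

## Problem sizes and numerical choices

The simulation-based checks use sizes chosen to make Monte-Carlo error
small relative to the tolerances they assert: 500 replicates of K = 15
studies × 200 patients for bivariate parameter recovery and region coverage
(mean absolute bias below 0.05 logits; coverage in [0.92, 0.98]); 1000
replicates for DerSimonian–Laird τ² recovery, with the tolerance computed
from the replicate spread (3 Monte-Carlo standard errors); n = 2000 for the
adjusted-ROC null and reduction checks (±0.03). Exhaustive oracles (all
pairs for the AUC, all cutpoints for Youden) run on 200 random small
studies. The whole suite completes in well under two minutes on one core.

Other numerical conventions: Youden ties break to the smallest threshold;
candidate cutpoints are midpoints of consecutive distinct values plus
sentinels; REML convergence at relative tolerance 1e-8 with boundary
truncation at zero; kernel densities use a Gaussian kernel with Silverman's
rule-of-thumb bandwidth; degenerate density panels (constant values) are
drawn as spikes with a warning; figures are tested through their exported
coordinate tables, never through rendered pixels.

## Known limitations

One covariate at a time in the adjusted analysis; no meta-regression inside
the bivariate model; no multiple-test comparative meta-analysis; no
prediction region on the SROC display (confidence region only); no
imputation — complete cases throughout; the two-stage normal approximation
rather than an exact binomial GLMM (an extension point, not a default); and
the adjusted analysis pools across studies as described above.
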