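Package: ipddta
Title: Individual Participant Data Meta-Analysis of Diagnostic Test Accuracy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for meta-analysis of diagnostic test accuracy from pooled
    individual participant data (IPD). Reads and validates pooled patient-level
    tables, dichotomizes continuous index-test results per study (user-supplied,
    common, or Youden-optimal thresholds), computes full per-study accuracy
    panels with confidence intervals, fits the bivariate random-effects model of
    logit sensitivity and specificity with its HSROC re-parameterization and
    summary ROC curve, pools per-study areas under the ROC curve with fixed- and
    random-effects models, and estimates covariate-adjusted ROC curves and the
    adjusted AUC from a semiparametric placement-value estimator. Includes a
    seeded synthetic-data generator, publication-style figures with exportable
    companion tables, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    ggplot2,
    metafor,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
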