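Package: cadrule
Title: Development and Evaluation of a Machine-Learned Rule-Out Test for
    Coronary Artery Disease
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested re-implementation of a clinical rule-out test
    development pipeline for coronary artery disease (CAD): univariate
    triple-test feature screening (Welch t-test, bootstrap-bounded ROC-AUC
    with an inverse-predictivity branch, permutation-normalised mutual
    information) on a sex-balanced subject subset; repeated stratified
    out-of-fold training of a bagged elastic-net plus random-forest stacked
    ensemble with sex-by-class sample weighting; per-sex decision cut points
    calibrated at a target sensitivity and subtracted so zero separates
    test-negative from test-positive; and a full evaluation suite (2x2
    performance, ROC-AUC, raw and confounder-adjusted odds ratios, NPV as a
    function of prevalence, subgroup analysis, permutation feature
    importance grouped by physiological category). A synthetic cohort
    generator reproduces the statistical structure the analysis assumes
    (class imbalance, sex-by-class confounding, heterogeneous feature
    effects) so every stage is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    ranger,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
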