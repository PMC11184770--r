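Package: ssbprisk
Title: Genetic Risk Modelling for Salt Sensitivity of Blood Pressure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for genetic risk analysis of salt
    sensitivity of blood pressure (SSBP) in case-control cohorts classified
    by the modified Sullivan acute oral saline load and diuresis shrinkage
    test. Provides genotype and sample quality control, additive-model
    logistic genome-wide association with covariates, greedy LD clumping, a
    summary-statistic transcriptome-wide association (TWAS) engine with
    multi-model eQTL weight training and locus-level conditional analysis,
    moderated-t differential expression, polygenic risk scores (PRS) and
    polygenic transcriptome risk scores (PTRS) at serial P-value thresholds
    with PCA-weighted score combination, covariate-adjusted quartile risk
    models with ROC/AUC and cross-validation, a case-control association
    power calculator, and a synthetic cohort generator that emulates the
    statistical structure of a saline-loading study so every stage is
    testable without access to individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    pROC,
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
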