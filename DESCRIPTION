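Package: methbench
Title: Multi-Cohort Blood DNA Methylation Analysis and Classifier Benchmarking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for multi-batch blood DNA methylation studies of
    depression-like case/control phenotypes: simulation of multi-cohort
    methylation data with planted effects, beta/M conversion and quantile
    normalization, reference-based cell-type deconvolution with residual+mean
    adjustment, parametric empirical-Bayes batch harmonization (ComBat),
    moderated-t differential methylation with a directional agreement index,
    Sidik-Jonkman random-effects meta-analysis, seven feature-selection
    strategies, a uniform classifier suite (penalized regressions, trees,
    SVMs, AdaBoost, and joint autoencoder-classifier networks), and a
    leakage-aware repeated cross-validation / batch hold-out evaluation
    framework that quantifies feature-selection bias.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    pracma,
    glmnet,
    ranger,
    rpart,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    sva
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
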