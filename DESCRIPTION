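Package: ehrfm
Title: Adaptation of Structured-EHR Foundation Models Across Hospital Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale framework for studying how autoregressive
    next-code foundation models for structured electronic health records
    transfer between hospital sites. Provides a two-site synthetic EHR
    generator with latent Markov patient-state structure and analytic
    oracles, an OMOP-lite timeline store, inpatient cohort construction
    with eight clinical prediction tasks, a miniature decoder-only
    local-attention transformer pretrained on next-code prediction (with
    continued pretraining for cross-site adaptation), frozen-encoder
    linear probes and count-featurized gradient-boosting baselines,
    few-shot and pretraining-subsample experiment protocols, and
    evaluation utilities (AUROC, quantile-binned expected calibration
    error with prior correction, hierarchical bootstrap model
    comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    Matrix,
    Rcpp,
    xgboost,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    pROC
Config/testthat/edition: 3
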