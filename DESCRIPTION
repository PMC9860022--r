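Package: serostack
Title: Stacked Ensemble Learning for Pre-Diagnostic Serum Biomarker Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating multi-marker early-detection
    classifiers from pre-diagnostic serum biomarker panels in nested
    case-control cohorts. Implements Firth bias-reduced logistic regression
    with profile penalized-likelihood inference for single-feature
    association and ranking; a heterogeneous layer of ten base classifier
    families trained by repeated stratified cross-validation with minority
    oversampling and random hyperparameter search; stacked meta-learners
    (BIC-weighted Bayesian model averaging, arithmetic/geometric mean,
    maximum, and averaged neural networks) in joined and single
    time-to-diagnosis group architectures; ROC operating-point analysis at
    fixed specificity with stratified bootstrap inference; model-agnostic
    partial-dependence feature importance; external validation under random
    imputation of never-collected covariates; and a synthetic cohort
    generator emulating the structure of such studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    rpart,
    nnet,
    glmnet,
    xgboost,
    ranger,
    e1071,
    kernlab,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
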