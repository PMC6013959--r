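Package: readmitnet
Title: 30-Day Hospital Readmission Risk Prediction with Deep Unified Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting 30-day hospital readmission risk from
    electronic medical record (EMR) data. Implements deep unified networks
    (DUNs), a mesh-like feed-forward architecture in which every inner layer
    is fused with the raw input by a harmonizing unit and a per-sample
    attention unit mixes the layers on a probability simplex before a single
    decision unit, together with maxout-network, penalized logistic
    regression and gradient-boosting baselines. Includes a seeded synthetic
    EMR cohort generator, index-admission/readmission labeling with
    exclusion rules, windowed feature extraction with bag-of-words note
    features, min-max scaling, total Kullback-Leibler divergence variable
    filtering, threshold-sweep ROC evaluation with stratified k-fold cross
    validation, and a telemonitoring cost-savings model swept along ROC
    curves.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    pROC,
    xgboost,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
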