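Package: panmtl
Title: Multi-Task L2,1-Regularized Logistic Regression for Pan-Cancer
    Expression Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-class classification of normalized gene-expression
    profiles by regularized multi-task learning. Each class (e.g. a tumor
    type) becomes a one-vs-rest logistic task over a shared predictor
    matrix; an L2,1 row-group penalty selects genes jointly across all
    tasks and a squared-Frobenius ridge term stabilizes the fit. The
    composite objective is minimized by an accelerated proximal-gradient
    (FISTA) solver with backtracking. Includes evaluation metrics for
    imbalanced multi-class problems (multiclass Matthews correlation
    coefficient, cross-entropy log loss, per-class precision/recall/F1,
    one-vs-rest ROC and precision-recall curves), coefficient-based and
    minimum-redundancy-maximum-relevance (mRMR) gene ranking, stratified
    splitting and repeated stratified cross-validation for penalty
    selection, and a seeded generator of VST-scale synthetic expression
    data with planted class-specific signal genes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    glmnet,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
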