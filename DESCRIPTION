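Package: confaudit
Title: Confounding Audits for Medical-Imaging Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates observational radiograph cohorts in which patient traits
    drive disease risk and disease status drives hospital-process triage, so
    that acquisition metadata confounds image-based disease classifiers.
    Provides the full audit pipeline: scalar-variable cleaning, binarization
    and imputation; a deterministic filter-bank image featurizer with PCA
    reduction; logistic, linear and kernel Naive Bayes models over
    combinatorial predictor sets; Gower-dissimilarity greedy case-control
    matching; and ROC/AUC machinery with DeLong variance, paired and unpaired
    AUC comparison tests, Youden operating points, stratified bootstrap
    intervals and Fisher exact association tables. The headline experiment
    measures how an image-only classifier's AUC collapses to chance when
    case-control matching removes confounder-disease associations from the
    test set.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    glmnet,
    Matrix,
    png,
    jsonlite,
    yaml,
    MASS,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    pROC,
    cluster,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
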