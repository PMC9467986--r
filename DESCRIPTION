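Package: dynconn
Title: Dynamic Functional Network Connectivity States and Suicidality Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tested pipeline for dynamic functional network connectivity
    (dFNC) analysis of multivariate component time courses: group temporal
    decomposition (two-stage PCA, Infomax ICA with stability resampling,
    back-reconstruction, noise-component screening), sliding-window
    graphical-LASSO-regularized Fisher-z connectivity, K-means connectivity
    states with elbow model selection and dwell-time / fraction-time /
    transition metrics, edgewise two-sample group statistics with
    false-discovery-rate control, and per-state support-vector-machine
    classification with F-score feature ranking, leave-one-out
    cross-validated grid search and permutation significance. A synthetic
    state-switching cohort generator with known ground truth makes every
    stage verifiable without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    e1071,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
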