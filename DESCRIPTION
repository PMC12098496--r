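Package: gradstates
Title: Dynamic Connectivity States and Functional Gradients for
    Resting-State fMRI Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sliding-window dynamic functional connectivity analysis with
    k-means brain-state decomposition (elbow, silhouette and
    Calinski-Harabasz model selection), diffusion-map functional-gradient
    estimation with Procrustes alignment and gradient dispersion,
    covariate-adjusted mass-univariate group statistics with FDR and
    permutation cluster correction, and multi-classifier cross-validated
    evaluation. Includes a synthetic two-group cohort generator with
    Markov-switching covariance states and a planted one-dimensional
    connectivity manifold, so the full pipeline is testable end to end
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    yaml,
    igraph,
    cluster,
    class,
    e1071,
    randomForest,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
LinkingTo: Rcpp, RcppArmadillo
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
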