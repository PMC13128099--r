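Package: progphen
Title: Graph-Based Disease-Progression Subphenotyping from Longitudinal EHR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying disease-progression subphenotypes from
    longitudinal electronic health records. Builds directed patient graphs
    linking clinically similar encounters across patients, learns
    outcome-oriented node embeddings with directed graph neural networks
    (including a magnetic-Laplacian spectral convolution), clusters per-patient
    embedding sequences with dynamic-time-warping K-means, and characterizes the
    resulting subphenotypes with Kaplan-Meier survival analysis, prevalence
    contrasts, and pre-index predictive modelling. Ships a seeded synthetic
    EHR generator with planted progression subphenotypes so the full pipeline
    is testable without access to protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    glmnet,
    jsonlite,
    pROC,
    stats,
    survival,
    utils,
    xgboost,
    yaml
LinkingTo: Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
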