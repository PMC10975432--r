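Package: cuticleqspr
Title: QSPR Modeling of Plant Cuticle-Air Partition Coefficients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style toolkit for quantitative structure-property
    relationship (QSPR) modeling of the plant cuticle-air partition
    coefficient (log Kca) of organic pollutants. Computes a small set of
    2D graph-spectral molecular descriptors from SMILES (Laplacian and
    adjacency eigenvalue descriptors, Burden and Barysz matrix
    descriptors, lead-like rule scores), builds and splits measurement
    datasets, fits multiple linear regression and nonlinear learners
    (distance-weighted KNN, gradient-boosted trees, neural network) with
    grid-searched cross-validation, runs a full validation battery
    (leave-one-out and bootstrap Q2, external metrics, concordance
    correlation), delimits a leverage-based applicability domain
    (Williams plot), and attributes predictions to descriptors with
    exact coalition-enumeration Shapley values. A synthetic-data
    generator emulates the replicate structure of measured Kca
    compilations so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    igraph,
    ChemmineR,
    ChemmineOB,
    rpart,
    nnet,
    generics,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
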