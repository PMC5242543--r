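Package: polyconn
Title: Polynomial Structure-Function Mapping of Brain Connectivity with
    Persistent-Homology Model Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits resting-state functional connectivity as a Tikhonov-
    regularized weighted sum of powers of the structural connectivity
    matrix plus a global shared input, with the regularization weight
    chosen by generalized cross-validation and coefficient uncertainty
    quantified by bootstrap resampling. Mapping quality is assessed with
    a threshold-free similarity measure based on zeroth-Betti-number
    persistence barcodes of the 1-|correlation| filtration, alongside
    Frobenius and Pearson comparisons, path-length scans with automatic
    elbow selection, degree-preserving rewiring null models, and
    Gaussian rank resampling of edge weights. Includes seeded synthetic
    generators for structural graphs, forward-model functional matrices,
    and correlation matrices, plus a command-line pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
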