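Package: rnascape
Title: Guided Boltzmann Sampling and Coarse Graining of RNA
    Secondary-Structure Energy Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Adaptive exploration of RNA secondary-structure energy landscapes
    by Boltzmann sampling under iteratively accumulated repellent base-pair
    pseudo-energies. Provides a self-contained pair-plus-stack energy model,
    dynamic programming for minimum free energy folding (with hard
    constraints), partition functions and stochastic backtracking under soft
    constraints, exhaustive enumeration of conformation spaces, gradient
    walks and gradient basins, barrier trees by exhaustive flooding with
    energy-based coarse graining, two-dimensional base-pair distance-class
    projections with coverage measures, and ensemble diversity metrics
    (density of states, weighted mean base-pair distance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
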