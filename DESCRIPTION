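Package: fptreg
Title: Temporal Precision of Threshold Crossing in Regulated Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: First-passage-time analysis of threshold-crossing events for a gene
    product whose production is regulated by an accumulating activator or a
    diminishing repressor. Provides an exact master-equation solver with an
    absorbing boundary at the target threshold (block-structured generator,
    moment formula via sequential linear solves), closed-form variance
    approximations and optimal-regulation formulas in the sharp-switch limit,
    an exact stochastic simulator with geometric production bursts, regulator
    birth-death dynamics and binomial partitioning at cell division, and a
    cross-sectional scatter-data pipeline (bin-based timing statistics and a
    trapezoidal linearity index) with a synthetic single-cell scatter
    generator emulating destructive smFISH-style measurement.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    deSolve,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
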