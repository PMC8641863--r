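Package: fflnoise
Title: Noise Reduction and Signal Transduction in Isolated and Coupled
    Feed-Forward Loop Motifs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Systematic comparison of noise filtering and signal transduction
    across isolated and pairwise-coupled feed-forward loop (FFL) motifs
    modelled as post-translational activation/inactivation reaction networks.
    Enumerates all admissible motif topologies and AND/OR gate assignments,
    compiles them into mass-action chemical reaction networks with conserved
    totals per layer, drives them with a calibrated super-Poissonian input
    staircase, and computes time-dependent and stationary means and
    covariances by the linear noise approximation. A Gillespie stochastic
    simulator and a truncated chemical-master-equation solver validate the
    approximation on small instances. Noise (percent coefficient of
    variation, Fano factor) and signal-transduction (input-output slope)
    metrics and catalog-wide rankings are produced as tidy tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils,
    xml2,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
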