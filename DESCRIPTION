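Package: switchscape
Title: Quasi-Potential Landscapes, Switching Times and Bifurcation
    Sensitivity for Bistable Mass-Action Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing deterministic and stochastic descriptions of
    bistable biochemical reaction networks. From a single mass-action network
    description the package derives the deterministic vector field and the
    volume-scaled Markov jump process, locates saddle-node bifurcations by
    continuation, estimates mean first-passage times between metastable states
    with an exact Gillespie stochastic simulation algorithm, and computes
    quasi-potential barrier heights with a geometric minimum action method on
    the jump-process Hamiltonian. Local (percent-perturbation) and variance
    based (Sobol total-effect) parameter sensitivity spectra can be computed
    for each of the three outputs and compared by Spearman rank correlation.
    Ships bistable test fixtures (the Schlogl trimolecular network, a
    two-species shuttle variant, and a synthetic mitochondrial-apoptosis-like
    switch) and a reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
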