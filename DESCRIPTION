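Package: cpim
Title: Contact-Process Ising Model Simulation and Spatial Analysis of
    Two-State Cell Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic lattice simulation of growing bacterial colonies
    whose cells carry a two-state, chemically coupled gene network: a
    contact process (colonization, differentiation, death) hybridised
    with Ising-model Metropolis spin dynamics among differentiated
    cells (the CPIM), together with the quantitative analysis stack for
    the resulting patterns.  Includes magnetization and susceptibility
    observables with finite-size scaling, masked radial spatial
    autocorrelation with exponential-decay and power-law fits,
    connected-cluster extraction with discrete power-law exponent
    estimation (maximum likelihood with automatic low-end cutoff, and
    least squares on log-binned densities), rotation-minimised Hamming
    comparison of binary patterns, and a two-state thermodynamic
    promoter-occupancy dose-response model for bistable toggle-switch
    circuits coupled by quorum-sensing signals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    minpack.lm,
    jsonlite,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    withr
Config/testthat/edition: 3
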