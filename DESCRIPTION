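Package: toxkinsim
Title: Simulation-Based Evaluation of Toxicokinetic Exposure Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates virtual rodent toxicology studies under population
    pharmacokinetic models (one-compartment, one-compartment with
    Michaelis-Menten elimination, two-compartment) with sparse composite or
    serial toxicokinetic sampling, estimates systemic exposure (24-h AUC,
    Cmax, time above a threshold concentration, cumulative 6-month AUC) by
    non-compartmental analysis and by a first-order conditional (FOCE-I)
    nonlinear mixed-effects estimator, and quantifies the bias (scaled
    relative mean error) and precision (coefficient of variation) of each
    method across simulation replicates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
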