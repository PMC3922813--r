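Package: coevonet
Title: Co-Evolution of Cooperation and Link Dynamics on Interdependent Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the co-evolution of strategies and network
    structure in the donation-game prisoner's dilemma on two interdependent
    populations. Provides the embedded Markov chain over link types induced by
    break-and-rewire linking dynamics (transition matrix, closed-form and
    numeric stationary distributions), the fast-rewiring mean-field layer
    (rescaled payoff matrix, average fitness, Fermi pairwise-comparison
    transition rates, the extended replicator field, Jacobians, equilibrium
    classification, the critical benefit-to-cost ratio, the unstable interior
    fixed point and the critical intra-group attaching bias), an exact
    stochastic agent-based simulator with a compiled core, and experiment
    drivers (phase portraits, intra-group-bias sweeps, initial-fraction
    sweeps) that return tidy tibbles and ggplot2 figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
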