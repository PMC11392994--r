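Package: anttrails
Title: Stochastic Lattice and Continuum Models of Ant Trail Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates foraging ant colonies as interacting random walkers on a
    lattice coupled to a pheromone field governed by a reaction-diffusion
    equation, together with a macroscopic chemotaxis PDE solved by an
    alternating direction implicit (ADI) scheme and the linear-stability
    machinery (dispersion relations of the space-averaged system) that
    predicts when the homogeneous state destabilizes into trails. Includes
    scenario presets for single and multiple food-source environments,
    trail-formation metrics, and tidy accessors and plots for all result
    types.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
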