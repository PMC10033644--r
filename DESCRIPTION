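Package: alleeCM
Title: Dynamics and Turing Patterns of a Diffusive Predator-Prey Model
    with Allee Effect and Crowley-Martin Functional Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the full dynamical analysis of a two-species
    predator-prey model in which prey growth is subject to a multiplicative
    Allee effect and predation follows the Crowley-Martin functional
    response. Enumerates boundary and coexistence equilibria through the
    quartic reduction of the nullcline system, classifies local stability,
    locates Hopf and saddle-node (fold) bifurcations in the capture-rate
    parameter, computes separatrices and basins of attraction in the
    bistable regime, performs the linearized Turing analysis (dispersion
    relation, instability conditions, unstable wavenumber band), and
    simulates the two-dimensional reaction-diffusion system with an
    explicit Euler scheme under zero-flux boundary conditions, including
    morphological classification of the emerging spot, stripe and
    labyrinthine patterns.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
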