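Package: cylcond
Title: Monte Carlo Study of Counterion Condensation on a Charged Cylinder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Metropolis Monte Carlo simulation of pointlike counterions around a
    uniformly charged cylinder in a cylindrical cell with one-dimensional periodic
    boundary conditions, using a Lekner-type resummation of the Coulomb
    interaction. Provides observables for the Manning condensation transition and
    the complete-condensation transition (condensed fraction, dimensionless heat
    capacity with blocking errors, rescaled radial density profiles), analytic
    reference theory (salt-free Poisson-Boltzmann cell model, strong-coupling
    two-state prediction, needle-limit density profile, complete-condensation
    onset formulas), and finite-size scaling tools (power-law exponent fits and
    two-parameter data collapse with bootstrap errors).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
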