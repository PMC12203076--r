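Package: anammoxiso
Title: Nitrogen and Oxygen Isotope Systematics of Anammox Batch Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Forward modelling and Bayesian inference of nitrogen and oxygen
    kinetic isotope effects during anaerobic ammonium oxidation (anammox).
    Implements exact atom-fraction mass-balance ordinary differential
    equations for the NH4+, NO2- and NO3- pools under zero-order anammox
    kinetics, including abiotic and anammox-mediated oxygen isotope exchange
    between NO2- and water and an optional backward flux of NO2- oxidation.
    Provides closed-form nitrite-water oxygen equilibration kinetics, the
    regression-slope to exchange-fraction calculus for labelled-water
    experiments, closed-system Rayleigh estimators, staged adaptive
    Metropolis MCMC estimation of isotope effects and the exchange rate
    constant, a synthetic batch-culture data generator, and scenario
    exercises (produced-nitrate delta15N, pool mixing, combined oxygen
    effects, dual-isotope trajectories, backflux falsification).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
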