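Package: redoxclock
Title: Stochastic Amplitude-Phase Models of Coupled Circadian Redox Oscillators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of ensembles of stochastic Poincare
    (amplitude-phase) oscillators with twist, modelling circadian redox
    rhythms of mitochondrial hydrogen peroxide. Provides a seeded
    Euler-Maruyama integrator with a compiled core, mean-field coupling
    between oscillators, forcing by a Goodwin-like transcription-translation
    feedback loop (TTFL) model, and the analysis toolkit needed to study
    desynchronization, synchronization and entrainment: Kuramoto order
    parameter, circular statistics, zero-crossing and periodogram period
    estimation, phase-dispersion dynamics, mean-field amplitude, bootstrap
    Lowess sweep summaries, and estimators for the amplitude relaxation rate
    and twist parameters.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
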