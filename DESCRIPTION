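Package: gutdrift
Title: Stochastic Colonization Dynamics of Host-Associated Microbial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of stochastic bacterial colonization of
    a host intestine, modeled as a multi-strain birth-death-immigration
    process with logistic saturation at a shared carrying capacity. Provides
    exact Gillespie and tau-leaping simulation of per-host community
    assembly, the analytic regime theory (establishment and growth
    timescales, founder extinction probability, the colonization-to-birth
    rate ratio controlling bimodal versus unimodal between-host community
    composition), the sample bimodality coefficient with bootstrap
    confidence intervals and threshold-crossing detection, calibration
    routines (logistic growth fits, death-rate estimation from
    division-arrest decay, colonization- and feeding-rate estimation from
    short-time assays), and seed-deterministic synthetic-data generators
    with a dilution-plating observation model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
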