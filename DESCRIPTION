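Package: actonem
Title: Multiscale Modeling of Motor-Driven Active Nematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools linking the microscopic kinetics of molecular-motor
    clusters to the hydrodynamics of cytoskeletal active nematics. Provides
    an exact stochastic (Gillespie) simulator of the three-state catalytic
    cycle of multi-headed motor clusters walking on one or two actin
    filaments, with single-filament velocity/run-length and two-filament
    strain-rate and crosslinking statistics; a scaling model mapping strain
    rate and crosslink probability to activity, crosslinker-augmented
    elasticity, nematic speed and length scale, including peak diagnostics
    and a Michaelis-Menten alternative; flow-field statistics (mean/rms
    speed, velocity correlation length, vorticity, vortex radius by
    correlated displacement velocimetry); a reduced hybrid lattice-Boltzmann
    / Beris-Edwards simulator of two-dimensional active nematic
    hydrodynamics; and synthetic-data generators for vortex-structured
    velocity fields and microscopic rate curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
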