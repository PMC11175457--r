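Package: sitwalk
Title: Predictive Neuromuscular Simulation of the Sit-to-Walk Movement
Version: 0.1.0
Authors@R:
    person("sitwalk", "developers", email = "sitwalk@example.org", role = c("aut", "cre"))
Description: A planar (sagittal) neuromusculoskeletal simulator for the
    sit-to-walk movement. Provides an 11 degree-of-freedom, 20-muscle
    rigid-body model with Hill-type muscle-tendon units, Hunt-Crossley
    compliant chair and ground contact, a two-phase delayed-reflex
    stand-up controller chained into a reflex-based gait controller,
    a composite movement objective (trajectory corridor, gait velocity,
    joint range, head acceleration, metabolic energy), and a CMA-ES
    shooting optimizer, so that stand-up-and-walk movements are
    generated de novo under configurable seat heights and initial
    postures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
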