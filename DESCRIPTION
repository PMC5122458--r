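Package: choanotaxis
Title: Aerotaxis Modelling and Trajectory Analysis for Swimming Microorganisms
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying oxygen-gradient navigation (aerotaxis) of
    swimming microorganisms such as choanoflagellate colonies. Includes a
    finite-volume simulator for oxygen diffusion in a PDMS microfluidic
    device with switchable gas channels, a one-dimensional Keller-Segel
    population solver with pluggable gradient-response functionals
    (absolute-gradient and logarithmic/relative-gradient sensing) and
    least-squares fitting of its parameters, Langevin simulators and
    Fokker-Planck steady states for deterministic-steering and stochastic
    (rotational-diffusion modulation) navigation strategies, turn-angle
    distribution analytics with maximum-likelihood fitting, trajectory
    statistics (boundary-corrected density profiles, velocity and angle
    series), a minimal colony tracker (running-median background, band-pass
    detection, proximity linking), and a synthetic-data generator producing
    trajectories, kymographs and toy videos with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
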