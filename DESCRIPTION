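Package: lvadsim
Title: Multiscale Simulation of Heart Failure and Continuous-Flow LVAD
    Hemodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale multiscale model of ventricular electromechanics
    coupled to a closed-loop lumped cardiovascular circulation with a
    continuous-flow left ventricular assist device (LVAD). Includes a human
    ventricular ionic cell model paced at fixed cycle length, a 1D monodomain
    cable for conduction-velocity studies, a cross-bridge myofilament model
    converting calcium transients into active tension and ATP consumption, an
    exponential (Fung-type) passive constitutive law, activation-driven 0D
    ventricle surrogates embedded in an eight-compartment circulation, and a
    hemodynamic summarizer (pressure-volume loop indices, stroke work,
    condition-vs-condition percent changes). Ships normal, heart-failure and
    heart-failure-plus-LVAD scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
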