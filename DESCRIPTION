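Package: cablefit
Title: Passive Cable Parameter Fitting for Compartmental Neuron Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Compartmental modelling toolkit for estimating the passive
    membrane parameters of neurons -- specific membrane capacitance (Cm),
    specific membrane resistivity (Rm) and axial resistivity (Ra) -- from
    somatic voltage transients. Provides an SWC morphology reader with
    frustum-based surface areas, a branched-cable simulator (Crank-Nicolson
    time stepping with a direct Hines tree solve, Hodgkin-Huxley sodium and
    potassium channels, Ih, and kinetic AMPA/NMDA synapses with magnesium
    block), a global dendritic-spine membrane-area correction, RMSD-based
    transient fitting with constrained-parameter profiles, balanced-bootstrap
    statistical and morphology-perturbation systematic error estimation,
    nucleated-patch specific-capacitance estimation, functional-consequence
    protocols (EPSP transfer, synapse-count-to-spike, axonal conduction
    velocity), and synthetic-data generators for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm,
    lhs
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
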