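Package: isletdyn
Title: Coupled Glucose-Insulin and Beta-Cell-Cycle Dynamics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulator and analysis toolkit for an eight-state ordinary
    differential equation model coupling blood glucose and insulin
    concentrations to the pancreatic beta-cell cycle and to a
    packet-distribution insulin storage in the tradition of Grodsky's
    threshold hypothesis. Provides the model right-hand sides, closed-form
    and numerically refined steady states with eigenvalue-based stability
    classification, a positivity (invariance) checker, adaptive Runge-Kutta
    time integration with a built-in scenario library (physiological,
    glucose infusion, type-1-like and type-2-like diabetes), trajectory
    feature extraction (local extrema, biphasic insulin release,
    glucose-curve comparison), and an independent threshold-density
    method-of-lines oracle that verifies the two-compartment storage
    reduction at constant glucose. Includes configuration and trajectory
    input/output and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
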