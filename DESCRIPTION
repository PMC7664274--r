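Package: clampkit
Title: Simulation and Quantification of Patch-Clamp Electrophysiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying whole-cell patch-clamp recordings from
    cortical neurons: action-potential detection and per-spike feature
    extraction from current-clamp step families, sodium-current I-V curves
    with Goldman-Hodgkin-Katz permeability and Boltzmann gating fits from
    voltage-clamp families, persistent-current analysis on slow voltage
    ramps, spontaneous IPSC event detection with pooled-ECDF comparisons,
    liquid-junction-potential calculation by the Henderson equation, and
    group inference with a two-stage false-discovery-rate step-up plus
    Kaplan-Meier survival comparisons. Ships single-compartment conductance
    and channel-kinetics simulators that generate every input class with
    known ground truth, so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    survival,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
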