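Package: hifpulse
Title: Pulsatile HIF-PHD Negative-Feedback Dynamics in Single Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ordinary differential equation models of the delayed negative
    feedback between hypoxia-inducible factor alpha (HIF) and the prolyl
    hydroxylase domain proteins (PHD1-3), the oxygen sensors that target HIF
    for degradation. Provides a generic two-component model and an
    isoform-resolved four-component model with piecewise-constant oxygen
    protocols (de-oxygenation, re-oxygenation), equilibrium computation and
    basal-synthesis calibration to a prescribed PHD steady-state ratio;
    least-squares fitting of the two-component model to single-cell
    fluorescence time series with an error-envelope fit classifier and a
    median-cell population workflow; trace analysis (sliding-window smoothing,
    half-maximum threshold crossing, transient/prolonged/multiple response
    classification, cycloheximide-chase half-life estimation); one-at-a-time
    parameter sensitivity scans and in silico PHD knockouts; one-way coupling
    of the HIF output to a p53-Mdm2 negative-feedback oscillator through a
    HIF-dependent p53 degradation rate; and a seeded synthetic single-cell
    cohort generator for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
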