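Package: ventmotion
Title: Ventilator Waveform, Energetics and Regional Ventilation Analysis
    with a Bias-Flow Lung Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis of neonatal ventilator waveforms and regional
    ventilation: breath segmentation, tidal lung-motion metrics (time to
    peak and maximum slope of pressure, volume and flow waves), lung
    mechanics (driving pressure, dynamic compliance, equation-of-motion
    fits), energetics (per-breath energy, tidal mechanical power,
    respiratory-system mechanical energy, ventilatory efficiency index),
    static pressure-volume curve summaries, and electrical impedance
    tomography regional metrics (center of ventilation, relative
    aeration, unventilated fraction).  Includes a closed-form simulator
    of a continuous-bias-flow ventilator, patient circuit and
    single-compartment preterm lung, a closed-loop ventilation protocol
    controller with CO2 kinetics, cohort generation with ground-truth
    parameters, and the cohort statistics layer (Welch t tests, one-way
    ANOVA with Tukey post hoc, balanced repeated-measures ANOVA).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
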