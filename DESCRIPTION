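Package: planteis
Title: Impedance Spectroscopy of Plant-Cell Suspensions with the Unified
    Randles-Debye Circuit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation, asymptotic analysis and complex nonlinear
    least-squares fitting of ultra-wide-band (4 Hz - 20 GHz) electrical
    impedance spectra of plant cell suspensions, modelled by a unified
    Randles-Debye equivalent circuit. Provides the closed-form pole/zero
    ladder of the seven-region Bode skeleton, the negative phase-peak
    observables phi4 and phi6 with their concentration and media
    dependence, the region-5 deviation metric d, a seeded synthetic-data
    generator emulating tomato (MSK8) and tobacco (BY2) suspensions in
    MS and phosphate-buffer media, spectrum CSV input/output, and a
    command-line interface chaining simulate, fit, analyze, compare and
    sensitivity steps.
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
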