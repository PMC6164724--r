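Package: qcmcoag
Title: Blood Coagulation Time Measurement from QCM Dissipation Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Signal-processing pipeline for point-of-care blood coagulation
    testing with a quartz crystal microbalance (QCM) operated in dissipation
    mode. Provides the physics of the liquid- and film-loaded shear resonator
    (shear-wave sensing depth, Kelvin-Voigt dissipation shift), a seeded
    simulator of coagulation dissipation traces, emulation of the calibrated
    quadrature-demodulation frequency sweep, resonance-curve fitting with
    3 dB bandwidth extraction of the dissipation factor D = BW/fs, clot-time
    (APTT/PT) endpoint detection by the peak of the first derivative of the
    dissipation curve, and linear cross-calibration of device clot times
    against a reference hemostasis analyzer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
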