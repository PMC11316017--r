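Package: rardose
Title: Radio-Adaptive Response Biodosimetry from Biomarker Dose-Response
    Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the radio-adaptive response (RAR) of
    animals given a small acute priming dose of thermal neutrons before a
    larger challenge dose. Fits per-biomarker dose-response calibration
    curves (linear, exponential, quadratic) over the acute-exposure
    groups, inverts them to estimate the RAR equivalent dose (RARED) of a
    primed-plus-challenged group, and derives the dimensionless RAR
    factor (RARF) and the priming-dose difference fraction. Includes a
    synthetic-study generator with known ground truth so every pipeline
    stage can be validated by parameter recovery, readers and writers for
    plain-text study files, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
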