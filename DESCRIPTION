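Package: capnodecay
Title: Ventilation-Driven Decay of Exhaled CO2 in Cardiac Arrest Capnograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing waveform capnography recorded during
    cardiopulmonary resuscitation. Detects ventilations during chest
    compression pauses, annotates the ensemble-plateau CO2 metric (epCO2)
    at a fixed delay from each expiratory upstroke, fits the per-ventilation
    geometric decay of exhaled CO2 (ep_n = a * k^n) by non-linear least
    squares, and applies a ventilation-rate normalization model that converts
    end-tidal CO2 measured at any ventilation rate to a reference rate. A
    synthetic multichannel episode generator (capnogram, compression depth,
    transthoracic impedance, ECG) with known ground truth supports
    end-to-end validation without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml,
    zoo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
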