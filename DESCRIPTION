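Package: seeqrs
Title: QRS Complex Detection with the Shannon Energy Envelope
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Detects QRS complexes (R-peaks) in single-lead or multi-lead
    electrocardiograms using a Shannon energy envelope pipeline: zero-phase
    Butterworth band-pass filtering (5-16 Hz), amplitude normalization,
    per-sample Shannon energy, z-standardization, a cascaded moving-average
    envelope, adaptive amplitude thresholding, and refractory-constrained
    R-peak localization in the filtered signal.  Includes a reader for WFDB
    header/signal records and plain-text single-lead signals, a beat-level
    evaluation harness (sensitivity, positive predictivity, accuracy and
    detection error rate with tolerance-window matching), a seeded synthetic
    ECG generator with P-QRS-T morphology and common noise classes
    (baseline wander, powerline interference, muscle noise, white noise),
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
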