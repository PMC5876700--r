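Package: ssvephase
Title: Decoding Phase-Encoded Steady-State Visual Evoked Potentials from Short EEG Epochs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature extraction and classification for phase-encoded
    steady-state visual evoked potential (SSVEP) brain-computer interfaces
    operating on short (0.5 s) multichannel EEG epochs. Implements
    maximum-likelihood phase estimation against a sinusoidal carrier,
    SVD-derived phase-class templates (correlation and template-phase
    features), one-period segment averaging with reference-segment
    correlation features, and SVD alignment of the occipital channels into a
    virtual channel. Classification uses a least-squares support vector
    machine with RBF kernel, Nelder-Mead hyperparameter tuning under
    stratified cross-validation, and Platt-calibrated posteriors; a
    dual-classifier arbitration scheme decodes joint frequency-and-phase
    targets. A synthetic SSVEP generator with 1/f noise makes the full
    pipeline testable without recorded EEG.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
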