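Package: ppgid
Title: Biometric Identification from Photoplethysmography Signals via
    Gram-Matrix Images and a CNN-LSTM Classifier
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for person identification from photoplethysmography (PPG)
    waveforms. Provides a parametric multi-subject PPG signal generator with
    per-subject beat morphology (systolic peak, dicrotic notch, diastolic
    peak), Savitzky-Golay smoothing and min-max normalization, conversion of
    1-D signals to 2-D Gram-matrix images, training-set augmentation by
    horizontal flipping with singular-value and principal-component
    perturbation and bounded rotation, a compact convolutional network with
    inverted-residual and squeeze-and-excitation blocks feeding an LSTM
    classification head (trained by backpropagation, no external deep
    learning runtime), evaluation reports (confusion matrix, per-class and
    macro/weighted precision, recall, F1), and a streaming identification
    loop that replays sample streams in place of a live sensor.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    EBImage,
    withr,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    caret,
    jsonlite,
    optparse,
    png
Config/testthat/edition: 3
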