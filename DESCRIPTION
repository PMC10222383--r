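Package: ecgverify
Title: ECG Biometric Verification with an Ensemble Siamese Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identity verification from single-lead electrocardiograms using
    an ensemble Siamese network. Provides a multi-subject synthetic ECG
    simulator with ground-truth R peaks, R-peak detection and beat
    segmentation, discrete-Fourier-transform feature augmentation (time
    channel plus magnitude-spectrum channel), balanced reference/probe
    bundle construction, a shared-weight one-dimensional convolutional
    encoder with an absolute-difference similarity head trained with binary
    cross-entropy and Adam, enrollment of new users without retraining via
    an embedding repository, and biometric evaluation (accuracy, false
    acceptance and rejection rates, equal error rate, detection error
    trade-off curves) under stratified k-fold cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
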