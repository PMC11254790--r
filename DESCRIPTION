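Package: heartbeatID
Title: Single-Heartbeat ECG Biometric Identification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-set human identification from single heartbeats in
    single-lead ECG. Provides a synthetic multi-subject ECG generator with
    known R-peak ground truth, WFDB and CSV record readers, resampling and
    Butterworth band-pass preprocessing, Pan-Tompkins QRS detection with
    rigid RR-length thresholding, fixed-length (150-sample) R-R beat
    extraction, SMOTE class balancing, a compact two-convolution 1D
    convolutional network classifier trained with Adam and early stopping,
    and macro-averaged multi-class evaluation, orchestrated by imbalanced
    (5-fold cross-validation) and balanced experimental scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'heartbeatID-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'synthetic.R'
    'io.R'
    'preprocess.R'
    'pantompkins.R'
    'segmentation.R'
    'balance.R'
    'cnn.R'
    'evaluate.R'
    'pipeline.R'
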