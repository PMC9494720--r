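Package: nirsgait
Title: Decoding Walking Intention from Multichannel fNIRS Hemoglobin Signals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classifies walking intention (step length and synchronous walking
    speed) from pre-movement functional near-infrared spectroscopy (fNIRS)
    hemoglobin time series. Implements morphological zero-drift removal,
    normalization to [-1, 1], rectangular-window power spectra, wavelet packet
    decomposition into 0.03 Hz subbands of the 0-0.18 Hz hemodynamic range
    with pre-onset slope features, a mean/coefficient-of-variation selection
    cascade with region quantization and cross-subject frequency statistics,
    one-way ANOVA filtering, and adaptive genetic-algorithm feature-subset
    search with support-vector-machine leave-one-subject-out fitness. A
    synthetic cohort generator with injectable class effects provides ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
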