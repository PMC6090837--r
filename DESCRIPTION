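Package: trfdecode
Title: Temporal Response Functions and Auditory Attention Decoding from EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of forward (encoding) and backward (decoding) temporal
    response functions that link continuous speech envelopes to multichannel
    EEG, with six estimators (ordinary least squares, Ridge, low-rank
    approximation, Shrinkage, first-derivative Tikhonov, and Elastic Net by
    coordinate descent), nested cross-validation with fold-model averaging,
    segment-wise auditory attention classification, ROC and Wolpaw/Nykopp
    information-transfer-rate metrics, a phase-randomization noise floor, the
    full EEG/audio conditioning chain (line-noise smoothing, FFT resampling,
    detrending, Butterworth highpass, joint-decorrelation EOG removal,
    zero-phase FIR bandpass, gammatone envelope extraction), and a seeded
    synthetic two-talker EEG simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    glmnet,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
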