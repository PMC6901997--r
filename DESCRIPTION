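Package: msfbcnn
Title: Multiscale Filter Bank Convolutional Networks for Motor Imagery EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end decoding of motor-imagery electroencephalography (EEG)
    with a parallel multiscale filter-bank convolutional neural network. The
    network stacks a bank of temporal convolutions at four kernel scales, a
    spatial convolution across electrodes, and a square/average-pool/log
    feature-reduction stage that computes log band power, followed by a
    convolutional classifier. Includes the standard motor-imagery
    preprocessing chain (Butterworth band-pass, polyphase resampling, epoch
    cropping, exponential moving standardization), intra-subject training
    with Adam and best-validation checkpointing, pooled cross-subject
    pretraining, layered-learning-rate fine-tuning for subject transfer with
    small calibration sets, and a generative simulator of event-related
    desynchronization (ERD/ERS) in the mu and beta bands for fully
    reproducible experiments without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
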