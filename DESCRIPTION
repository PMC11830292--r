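Package: pcgnet
Title: Heart-Sound Classification with a Customized 1-D Convolutional
    Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for binary classification of
    phonocardiogram (PCG) recordings into normal and abnormal heart
    sounds. Provides WAV reading/writing and band-limited resampling,
    zero-phase Butterworth band-pass filtering, fixed-length segmentation
    with wrap padding, pitch-shift augmentation for class balance, grouped
    stratified dataset splitting, a one-dimensional convolutional neural
    network trained with Adam on cross-entropy, evaluation via confusion
    matrices and ROC/AUC, a synthetic heart-sound simulator for fully
    reproducible experiments, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    signal,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
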