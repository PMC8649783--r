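Package: neurofuse
Title: EEG-EMG Input-Level Fusion with Convolutional Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for classifying the external task weight held during elbow
    flexion-extension from multi-channel electroencephalography (EEG) and
    electromyography (EMG) recordings. Provides a seeded synthetic-session
    generator with a 2 speed x 3 weight factorial trial structure,
    Butterworth band-pass preprocessing with marker-based movement
    segmentation, 250 ms sliding-window extraction, short-time Fourier
    transform spectrogram and time-domain signal images with several
    input-level fusion layouts (grouped, mixed, depth-stacked, and
    single-modality baselines), a compact convolutional neural network
    implementation (2D, split temporal-spatial, and 1D convolution
    families) with random-search hyperparameter tuning and early stopping,
    and a subject-specific evaluation protocol reporting accuracy,
    per-speed accuracy, confusion matrices, precision/recall and
    repeated-measures model comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
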