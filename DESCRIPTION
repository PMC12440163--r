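Package: gaitwise
Title: Multi-View Markerless Gait Impairment Classification from Pose Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying pathological gait patterns from 33-landmark
    pose time series extracted from mobile-phone video. Includes a kinematic
    simulator of seven gait classes (normal, circumduction, Trendelenburg,
    antalgic, crouch, Parkinsonian, vaulting) observed from frontal and
    sagittal camera views; preprocessing (gap interpolation, 30 fps
    resampling, rolling-median hip centring, frontal height rescaling,
    sliding-window segmentation); a catalogue of statistical, spectral,
    wavelet and entropy time-series features computed per keypoint channel;
    univariate relevance filtering with Benjamini-Yekutieli false discovery
    rate control; SMOTE class balancing; leave-one-subject-out nested
    cross-validation of SVM, random forest and gradient-boosted-tree
    classifiers with window-to-video majority voting and asynchronous
    multi-view vote fusion; and permutation feature importance aggregated to
    keypoint channels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    generics,
    ggplot2,
    stats,
    utils,
    Rcpp,
    e1071,
    ranger,
    xgboost,
    pracma
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
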