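Package: fatiguecg
Title: Mental Fatigue Classification from Single-Lead ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end pipeline for binary mental-fatigue assessment from
    single-lead 130 Hz electrocardiogram recordings. Provides a synthetic ECG
    generator with class-dependent RR-interval structure and visual-analogue-scale
    (VAS) fatigue trajectories; Daubechies-5 wavelet denoising with DC removal and
    z-scoring; 1-s segmentation, 10-s grouping, and short-time Fourier transform
    spectrograms; a hybrid classifier combining 1D/2D residual convolutional
    networks, bidirectional LSTMs and a transformer-encoder fusion of time-series,
    spectrogram and physiological (age/gender) features; classical and deep
    baselines (SVM, random forest, CNN, LSTM, BiLSTM); and a harness for 9:1
    train/test splitting, training, evaluation and feature-branch ablation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
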