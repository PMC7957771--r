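Package: eegemo
Title: Window Size and Electrode Arrangement Effects in CNN-Based EEG
    Emotion Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for studying how segmentation window size and
    electrode ordering affect subject-independent emotion recognition from
    multichannel EEG.  Provides a seeded generator of emotion-labelled
    synthetic EEG with continuous arousal-valence annotations (frontal alpha
    asymmetry coupled to valence, broadband beta gain coupled to arousal),
    bandpass/z-score preprocessing, majority-label windowing, Pearson
    correlation based channel orderings (MaxCBO/MinCBO), a 5 x 3 scalp grid
    input construction, compact 2D/3D convolutional classifiers trained with
    Adam, leave-one-subject-out and stratified k-fold evaluation with
    accuracy and the Matthews correlation coefficient, and the accompanying
    nonparametric comparison procedure (exact Wilcoxon signed-rank,
    Kruskal-Wallis, Benjamini-Hochberg FDR).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
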