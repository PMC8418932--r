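Package: eegfocus
Title: Focal EEG Discrimination with Tunable Q-Factor Wavelets and
    Binary Metaheuristic Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Discriminates focal from nonfocal electroencephalogram (EEG)
    recordings of the two-channel Bern-Barcelona style.  The channel
    difference is first-differenced and decomposed with a tunable Q-factor
    wavelet transform (TQWT) realised as an oversampled, perfectly
    reconstructing radix-2 filter bank.  Four entropies (log-energy,
    log of summed squares, SURE, and threshold) are computed per subband
    and assembled into a feature table.  Feature subsets are chosen by six
    binary metaheuristics (bat, differential evolution, firefly, genetic,
    grey wolf, and particle swarm) wrapped around classifier
    cross-validation accuracy, and six classifiers (k-nearest neighbour,
    RBF support vector machine, feed-forward, cascade-forward, generalised
    regression, and Elman-style recurrent neural networks) are scored with
    pooled stratified k-fold accuracy, sensitivity, and specificity.  A
    seeded generator of focal-like and nonfocal-like records makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
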