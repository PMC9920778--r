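Package: emgbnn
Title: Binarized Neural Network Gesture Recognition from Surface EMG Spectrograms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for surface-electromyography (sEMG) hand-gesture
    classification with a binarized convolutional neural network (BNN).
    Provides a synthetic sEMG trial generator (burst-modulated band-limited
    muscle activity with powerline hum and 10-bit quantization), STFT
    spectrogram preprocessing with hum-harmonic bin removal and a
    hardware-friendly L1 magnitude, binarization-aware training with exact
    folding of batch normalization and sign activation into integer
    thresholds, a bit-exact packed XNOR-popcount inference engine with
    OR-based pooling, and parameter/memory accounting for the packed model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite,
    yaml,
    data.table
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
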