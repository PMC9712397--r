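Package: eegattend
Title: Decoding Attention and Distraction from Naturalistic Multi-Channel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully reproducible pipeline for decoding attentional
    states (attention vs. distraction) from 32-channel EEG recorded in
    naturalistic settings where ground truth comes from second-observer video
    ratings. Covers fusion of multi-rater interval annotations by majority vote,
    blink-based EEG-to-video clock synchronization, preprocessing (downsampling,
    band-pass filtering, automated ocular-artifact regression, average
    re-referencing) and 2-s epoch extraction, orthogonal Daubechies discrete
    wavelet decomposition into canonical delta/theta/alpha/beta bands,
    channel-wise statistics with Benjamini-Hochberg FDR-corrected topography
    masks, and band-wise supervised classification (SVM, MLP, random forest,
    1D-CNN, LSTM) with leakage-guarded evaluation protocols and cross-dataset
    transfer. A first-class synthetic-data generator plants known band-amplitude
    effects, blink artifacts, clock offsets and noisy raters so that every stage
    is testable without any external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    e1071,
    ranger,
    data.table,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
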