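Package: birdcall
Title: Bird-Call Species Identification from Acoustic Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for identifying bird species from their
    calls. Generates labelled synthetic bird-call corpora (harmonic chirp
    syllables over noise), cleans recordings (high-pass filtering, noise
    gating, syllable-validity screening, silence trimming, 10 s / 0 dBFS
    standardization), extracts fused Mel-spectrogram and MFCC features
    (148 x 801 per clip), classifies with a coordinate-attention stacked-LSTM
    network trained by AdamW, and evaluates with per-species and aggregate
    accuracy, precision, recall, F1, pairwise AUC, top-5 accuracy and mean
    average precision, plus ROC curves and 2-D PCA embeddings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
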