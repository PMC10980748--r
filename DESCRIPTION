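Package: neuroalign
Title: Zero-Shot Alignment of Brain Embeddings and Language-Model Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether multielectrode neural activity patterns
    ("brain embeddings") share geometric structure with word embedding spaces
    from language models. Implements an intracranial signal preprocessing chain
    (despiking, common average referencing, wavelet high-frequency broadband
    power, zero-phase smoothing), lagged epoching into per-word electrode
    patterns, contiguous unique-word cross-validation folds, zero-shot linear
    encoding with nearest-neighbor and shuffle controls, an ensemble
    neural-network decoder scored by cosine-softmax ROC-AUC, resampling-based
    inference (bootstrap, permutation, FDR and Bonferroni control), and a
    synthetic-data generator with known ground-truth geometry for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
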