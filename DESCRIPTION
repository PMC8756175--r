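Package: TrioPPI
Title: Ternary Protein-Protein Interaction Prediction with Masked
    Multi-Parallel Convolutional Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sequence-based prediction of protein-protein interaction with a
    Siamese multi-parallel (multiscale) convolutional network trained on three
    classes: interacting pairs, non-interacting pairs and single proteins.
    Provides one-hot encoding with an explicit mask channel, dipeptide
    (k-let)-preserving sequence shuffling for negative-sample generation,
    AMSGrad training with Glorot initialization, occlusion-based per-residue
    importance maps, binary-classification metrics with stratified k-fold
    cross-validation, a synthetic motif-planted benchmark generator, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
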