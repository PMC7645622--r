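Package: voxppi
Title: Multimodal Protein-Protein Interaction Prediction from Voxelized
    Structures and Sequence Encodings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts protein-protein interactions by fusing two modalities
    of protein information: a voxel representation of the 3D backbone
    (one binary occupancy channel plus hydropathy, isoelectric-point and
    charge attribute channels) embedded through a pluggable structural
    embedder, and fixed-length sequence encodings (autocovariance and
    conjoint triad). A four-timestep LSTM consumes the per-pair structural
    channels, single-hidden-layer autoencoders compress the sequence
    encodings, and a sigmoid output layer classifies the fused feature
    vector. Includes readers for PDB backbone records, FASTA and pair
    tables, a synthetic-fixture generator with a planted, learnable
    interaction signal, and a full evaluation protocol (confusion metrics,
    MCC, AUROC/AUPRC, repeated stratified k-fold cross-validation and
    Welch's t-test).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    bio3d,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
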