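Package: interpeprank
Title: Graph-Network Scoring and Ranking of Peptide-Protein Docking Decoys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Re-scoring of rigid-body-docked peptide-protein decoys with an
    edge-conditioned graph convolutional network. Decoys are encoded as
    residue graphs with evolutionary node features (position-specific
    scoring matrix and self-entropy computed from a multiple sequence
    alignment) and physical edge features (peptide bonds and 4.5 Angstrom
    heavy-atom proximity). The network predicts a normalized ligand-RMSD
    quality bin for each decoy and a probability-weighted score used to
    rank decoys and select candidates for refinement. Includes CAPRI/DockQ
    model-quality metrics, ROC/precision-recall evaluation, a deterministic
    synthetic-fixture generator for building toy complexes, decoy sets and
    alignments, and a command-line interface covering the full
    featurize-train-score-select-evaluate workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
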