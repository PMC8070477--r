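Package: apmnet
Title: Cascade Graph Convolutional Scoring of Protein-Ligand Binding Affinity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores protein-ligand binding affinity (pKa, the negative decadic
    logarithm of Kd/Ki/IC50 in molar units) from the 2D topology of the binding
    pocket and the ligand. Molecules are featurized into 75-dimensional atom
    vectors and 6-dimensional bond vectors, pocket and ligand graphs are joined
    without cross edges, and a cascade graph network - linear embedding, ARMA
    spectral graph convolution stacks, an edge-conditioned message-passing
    layer, global add pooling and a dense head - regresses the affinity.
    Includes the full training recipe (smooth L1 loss, Adam, stepped learning
    rate, Glorot initialization), scoring and ranking-power evaluation metrics,
    PDBbind-style dataset assembly and splitting, and a synthetic complex
    generator with a planted affinity function so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    yaml,
    igraph,
    ChemmineR,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
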