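Package: surfppi
Title: Surface-Based Deep Graph Representation Learning for Protein-Protein Interaction Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protein binding sites and protein-protein interactions from
    molecular surface representations. Protein structures are read from PDB files,
    triangulated molecular surfaces are built from a probe-inflated Euclidean
    distance field, per-vertex chemo-geometric features (Fourier distance features,
    atom-type encodings, residue hydrophobicity, a hydrogen-bond surrogate, and
    principal curvatures from a locally fitted shape operator) are assembled, and a
    trainable point-cloud pipeline with learned radius-convolution kernels maps them
    to per-vertex interface-site scores and patch-pair interaction scores. Includes
    a seeded generator of geometrically and chemically complementary pseudo-protein
    pairs for end-to-end training and evaluation without external data, interface
    labeling at a fixed distance cutoff, balanced patch sampling, AMSGrad training
    with early stopping, and AUROC-based evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
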