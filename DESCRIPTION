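Package: spatomix
Title: Admixture-Aware Spatial and Single-Cell Transcriptomics of Tumor Microenvironments
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for joint single-cell and Slide-seqV2 analysis of tumor
    microenvironments: gene-set signature scoring, derivation and ROC
    evaluation of compact tumor signatures, Moran's I cell-type spatial
    autocorrelation, tumor/tumor-adjacent context segmentation, constrained
    linear-regression correction of bead admixture followed by pseudo-bulk
    negative-binomial differential expression, and ligand-receptor screening
    by label-permutation tests both on dissociated data (product of means)
    and on spatial k-nearest-neighbor graphs (antisymmetric neighborhood
    co-expression score). A synthetic-data module generates scRNA-seq-like,
    Slide-seq-like and bulk cohorts with known ground truth so every stage
    is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.3),
    SummarizedExperiment,
    SingleCellExperiment
Imports:
    methods,
    stats,
    utils,
    Matrix,
    MASS,
    pracma,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    pROC,
    ape,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
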