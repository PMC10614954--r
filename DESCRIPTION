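Package: scross
Title: Cross-Species Prediction and Comparison of Single-Cell Expression
    Profiles
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for integrating single-cell RNA-seq profiles across
    species and predicting how a cell's expression profile would look in
    another species. A conditional variational autoencoder with a
    zero-inflated negative binomial likelihood factors each cell's counts
    into cell-identity, species, batch and tissue components; swapping the
    species factor at decode time yields depth-normalized cross-species
    predictions. The package also provides the surrounding computation:
    one-to-one ortholog reconciliation from many-to-many homology edges,
    species demultiplexing of mixed-species barcodes, quality-control
    filters and pseudobulk utilities, prediction baselines and evaluation
    metrics, and X-chromosome-upregulation statistics (housekeeping
    normalization, per-cell log2 fold changes, XAR/XCR/autosome grouping,
    Wilcoxon tests, GGACH motif frequencies), plus a synthetic-data
    generator emulating multi-species ZINB counts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
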