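Package: screglink
Title: Single-Cell Gene-Peak Correlation Strength and Regulatory Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies cis-regulatory coupling between gene expression and
    chromatin accessibility in paired single-cell multiome (RNA + ATAC) data.
    Implements a neighborhood-inferred per-cell correlation strength index
    (a local bivariate spatial-association statistic computed on a weighted
    nearest-neighbor cell graph), together with gene-peak pairing by genomic
    window or transcription-factor binding sites, per-group feature-sparsity
    quality control, regulatory-marker detection between cell groups,
    pseudotime-binned regulation dynamics along trajectories, self-organizing
    map clustering of temporal regulation patterns, plotting utilities, a
    synthetic paired-multiome data generator with known ground-truth coupling,
    and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Matrix,
    tools,
    BiocGenerics,
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
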