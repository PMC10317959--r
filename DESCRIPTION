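Package: crisprTiling
Title: Design and Analysis of CRISPRi Tiling Screens over Regulatory Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for pooled CRISPR-interference screens tiled across
    transcription-factor-bound regulatory elements. Implements data-driven
    selection of a peak-significance cutoff from the knee of the FDR ECDF,
    consensus peak union, tiling sgRNA library design (NGG PAM scanning,
    restriction-site and spacing filters, two-pool assembly, cloning-oligo
    emission), validation-library design from primary-screen statistics,
    screen count normalization (control-median and TMM), an exponential
    fitness-score model of guide dropout fit by log-linear regression,
    robust rank aggregation of guide ranks into region scores, common and
    lineage-specific hit calling across cell models, binned occupancy-signal
    matrices with percentile clipping and k-means partitioning, and a
    synthetic-data generator with planted ground truth for parameter-recovery
    tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    edgeR,
    rtracklayer
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
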