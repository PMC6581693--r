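Package: cadence
Title: Chromatin Accessibility Dynamics and Expression Concordance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrative analysis of chromatin-accessibility and transcriptome
    dynamics across a differentiation time course. Builds consolidated peak
    atlases from replicate ATAC-seq peak sets (reciprocal-overlap concordance,
    summit-distance union merging, promoter/intragenic/intergenic partitioning,
    nearest-gene assignment), identifies differentially accessible or expressed
    features with a negative-binomial exact test and paired-consistency rescue,
    clusters z-scored temporal profiles by fuzzy c-means with automated cluster
    merging, performs bivariate transcription-factor footprinting (footprint
    depth and flanking accessibility) with Tukey-depth bagplot outlier calling,
    computes single-cell QC, highly-variable-gene selection, binary
    co-expression statistics (Jaccard similarity, Matthews correlation),
    regulon recovery-curve AUC activity and rank-based pseudotime summaries,
    and links assays through distance-binned hypergeometric concordance of
    accessibility and expression clusters and direct-target calling. A seeded
    synthetic-data generator emulates the statistical structure of each assay
    so the full pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    IRanges,
    S4Vectors,
    Matrix,
    grDevices,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    e1071,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
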