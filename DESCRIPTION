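Package: ampliDx
Title: Tiled-Amplicon Panel Sequencing and Exon-Resolution aCGH Toolkit
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computational core of a tiled-amplicon targeted sequencing
    diagnostic assay coupled with exon-resolution array comparative genomic
    hybridization (aCGH). Models redundant amplicon panel designs and their
    reportable range, assigns and aligns amplicon reads, soft-clips primer
    bases while reconstructing alignment coordinates, performs quality-aware
    pileup variant calling with coverage filters, low-level mosaicism
    detection and artifact-risk profiling, calls exon-level copy-number
    aberrations from probe log2-ratio tracks (centralization, scan-statistic
    segmentation, fuzzy-zero pruning, aberration filters), and computes
    assay-performance metrics. Ships a synthetic-data generator producing
    mini-genomes, tiled panels, reads with injected germline and mosaic
    variants (including under-primer polymorphisms causing allele drop-out),
    and aCGH probe tracks with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    BiocGenerics,
    rtracklayer,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    VariantAnnotation,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
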