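Package: mirforge
Title: Small RNA-Seq miRNA Discovery, isomiR Collapsing, and Two-Library
    Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for microRNA discovery and profiling from
    small RNA sequencing of two unreplicated libraries: read filtering and
    collapsing to unique tags, removal of other RNA classes, three-tier
    annotation against same-species and other-mammal precursor catalogs with
    novel hairpin prediction from genomic flanking sequence, isomiR family
    grouping with most-abundant-representative quantification, counts-per-
    million normalization with Fisher's exact test differential expression
    calls, and microarray-style validation utilities (probe median collapse,
    quantile normalization, replicate and cross-platform Pearson
    correlation). Ships a synthetic-data generator that plants pre-miRNA
    hairpins in a random genome with known abundances, fold changes, isomiR
    profiles and contaminating RNA classes, so every stage is testable
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    limma,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
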