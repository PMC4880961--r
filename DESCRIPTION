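Package: sRNAkit
Title: Small RNA Sequencing Analysis: Read Cleaning, miRNA Annotation,
    Hairpin Discovery, Target Rules and Stem-Loop RT-qPCR
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end toolkit for plant small RNA sequencing
    libraries. Raw reads are adapter-trimmed and assigned to a fixed set
    of removal categories with exact read accounting, then collapsed to
    unique tags with counts. Tags are profiled for length distribution
    and positional nucleotide bias, annotated against non-coding RNA
    reference sets with priority ordering, and matched to conserved
    mature miRNA catalogues with variant detection. Novel miRNA
    precursors are called from exact genomic mapping, block clustering
    and hairpin folding under a self-contained per-pair energy model
    with a dynamic-programming minimum-energy fold. Candidate
    miRNA/target duplexes are scored positionally with G:U wobble at
    half weight and filtered by six acceptance rules. Relative miRNA
    expression from stem-loop RT-qPCR is quantified by the 2^-ddCt
    method with replicate t tests. A synthetic-data module generates
    labelled reads, genomes with planted stem-loop precursors, and Ct
    tables with known fold changes, so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Sequencing, SmallRNA, GeneRegulation, qPCR
Collate: 
    'sRNAkit-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'utils.R'
    'annotation.R'
    'composition-stats.R'
    'folding.R'
    'novel-mirna.R'
    'qpcr.R'
    'read-processing.R'
    'pipeline.R'
    'synthetic-data.R'
    'target-prediction.R'
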