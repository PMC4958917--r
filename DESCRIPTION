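Package: idnaseq
Title: Immune DNA Signature Mining of TCRB CDR3 Reads from Bulk Exomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects sequencing reads that span rearranged T-cell receptor
    beta (TCRB) CDR3 junctions in bulk exome or transcriptome alignments and
    turns them into quantitative measures of T-cell infiltration. Provides
    germline V/J reference handling with conserved-anchor validation, a VDJ
    rearrangement and tumor-exome read simulator with ground-truth manifests,
    extraction of TCRB-window and unmapped reads from BAM files, an
    anchor-based CDR3 junction caller with clonotype aggregation and error
    collapse, cohort-level immune DNA (iDNA) decile scores, clonal diversity
    and clonality metrics, clonotype sharing, a closed-form detection
    sensitivity model with a Monte-Carlo cross-check, and multi-detector
    overlap benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
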