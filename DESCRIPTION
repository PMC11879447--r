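Package: hdnascan
Title: Detection and Genomic Enrichment Analysis of H-DNA-Forming Mirror Repeats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scans genome sequences for maximal mirror repeats and classifies
    the AG/CT-rich subset capable of forming intramolecular triplex (H-DNA)
    structures. Quantifies the distribution of detected motifs across
    chromosomes, annotated subcompartments (notably ribosomal DNA arrays),
    gene-anchored windows, and protein-binding-site windows, with
    fold-enrichment statistics, Fisher exact tests, and bootstrap confidence
    bands. Includes simplified short-tandem-repeat and G-quadruplex scanners
    for co-occurrence analyses, and a synthetic-genome generator that plants
    motifs with a machine-readable truth ledger so every pipeline stage can be
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
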