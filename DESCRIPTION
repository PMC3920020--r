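Package: mirloom
Title: Reference-Genome-Free Small RNA Annotation and Plant miRNA Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Toolkit for analysing plant small RNA sequencing libraries when no
    reference genome is available, using expressed sequence tags (ESTs) as the
    mapping reference. Implements read collapsing into unique reads, adapter
    and poly-nucleotide preprocessing, contaminant removal, a fixed-order
    annotation cascade (degraded mRNA, structural RNA families, conserved
    miRNAs), stem-loop precursor prediction from non-coding ESTs with
    structural filters and a minimum-free-energy prediction-interval filter,
    novel miRNA discovery requiring miRNA-star duplex evidence with 2-nt
    3-prime overhangs, complementarity- and homology-based target prediction,
    and tissue-specificity profiling of expression (reads per million and the
    specificity measure SPM). Includes a deterministic synthetic-data
    generator so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
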