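Package: siromics
Title: siRNA Off-Target Scanning and Multi-Omics Equivalence Assessment for RNAi Crops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing unintended effects of RNA-interference based
    genetically engineered crops against conventional breeding. Builds the
    exhaustive 21-24 nt mock siRNA k-mer library from a double-stranded RNA
    construct and scans transcript sets for Hamming-bounded off-target matches
    with a seed-and-extend index; profiles expressed small RNAs mapped exactly
    to the construct (size distribution, first-base coverage, base-preference
    matrices, GC and 5' A/U content); calls differentially expressed genes and
    differentially accumulated metabolites under fold-change and
    Benjamini-Hochberg adjusted p-value thresholds; provides Pareto scaling,
    PCA, hierarchical clustering and OPLS-DA variable importance; and runs
    hypergeometric pathway over-representation with fold-enrichment scores over
    a multi-line pairwise comparison design with shared/unique set logic. A
    synthetic-data module generates every input with known planted truth so the
    whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    BiocGenerics,
    ape,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
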