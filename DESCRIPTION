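Package: exosieve
Title: Hierarchical Map-and-Remove Classification of Short Plasma RNA-Seq Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to classify short (16-35 nt) plasma small-RNA sequencing
    reads into endogenous (host miRNA, transcripts, genome) and exogenous
    (microbiome, foreign miRNA, nucleotide collection) categories by a tiered
    "map and remove" cascade with configurable mismatch tolerance for the
    host tiers and exact matching for all exogenous tiers. Includes an exact
    pigeonhole k-mismatch short-read matcher, read preprocessing (adapter,
    length, quality and polyA filters), taxonomic resolution by best-hit
    lowest common ancestor with rRNA/tRNA masking and rank rollups, a
    synthetic-community read simulator with Illumina-like per-cycle
    substitution errors, and a closed-form model of coincidental matches to
    unrelated databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringi,
    readr,
    yaml,
    jsonlite,
    ggplot2,
    generics,
    methods,
    stats,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
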