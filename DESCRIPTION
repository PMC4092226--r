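Package: ovamir
Title: Ovarian Small RNA Annotation, Hairpin Prediction and miRNA Target Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for ovarian small-RNA sequencing studies in
    non-model crustaceans: read cleanup and collapsing into unique tags,
    five-group classification of tags against mature/precursor microRNA
    references and a surrogate genome, hairpin-based novel miRNA prediction
    with a built-in minimum-free-energy RNA folding engine, seed- and
    duplex-energy-based target-site discovery in 3'-UTRs, and relative
    expression statistics for qPCR (2^-ddCt against U6) and dual-luciferase
    reporter assays. Ships a seeded synthetic-data generator that plants
    miRNA hairpins, piRNA-like loci, contaminants and assay tables with full
    ground truth, so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    multcomp,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
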