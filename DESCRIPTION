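Package: polarmir
Title: Integrated miRNA-mRNA Correlation Analysis of Polarized Microglia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for integrated analysis of paired miRNA and mRNA
    expression profiles from polarization experiments (resting M0,
    LPS-driven M1, IL-4-driven M2a microglia or macrophages).
    Implements two-group differential expression with
    Benjamini-Hochberg adjustment, miRNA shortlist selection relative
    to a reference miRNA, per-miRNA Pearson correlation screening of
    candidate target genes, triple intersection with two predicted
    target databases, direction classification of the resulting
    miRNA:mRNA interactome, overlap statistics, and hypergeometric
    gene-set over-representation ranking. A planted-truth synthetic
    data generator emulates the 3-condition, 3-replicate study design
    so every pipeline stage can be tested without array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
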