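Package: cellcross
Title: Single-Cell Genotyping, Lineage Assignment and QTL/eQTL Mapping in
    Pooled Segregant Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for one-pot single-cell eQTL and QTL analysis of
    pooled haploid segregants. Sparse per-cell allele counts from
    ultra-low-coverage single-cell RNA-seq are turned into posterior
    genotypes with a two-state hidden Markov model, cells are assigned to a
    reference F2-segregant panel with a permutation null and doublet
    flagging, and per-strain consensus profiles feed an L0-penalised
    cross-validated forward search for QTL and per-gene eQTL. Restricted
    maximum likelihood (REML) variance-component models partition fitness
    variance among genotype, expression and shared components, and gene
    expression variance between cis- and trans-regulatory loci. Downstream
    analyses locate eQTL hotspots in 25-kb windows, classify eQTL as cis or
    trans, match QTL to eQTL by Needleman-Wunsch alignment, and score model
    similarity. A synthetic F2-cross generator with planted genetic
    architectures provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
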