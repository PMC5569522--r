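Package: medipscan
Title: Window-Based Differential DNA Methylation Analysis for Pooled MeDIP-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Comparative MeDIP-seq analysis between two populations
    sequenced as pools: fixed-width genomic window grids and fragment
    midpoint read counting, per-window negative-binomial exact tests with
    conditional-likelihood common-dispersion estimation, differentially
    methylated region (DMR) calling with p-value based edge extension and
    merging, sliding-window scanning for genomic DMR clusters, CpG-density
    and gene-proximity annotation, DMR set overlap and within-population
    pairwise validation, small-statistics utilities (chi-square tables,
    Bonferroni, noncentral-t power), and a synthetic-data generator with
    planted DMRs and clusters for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    edgeR,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
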