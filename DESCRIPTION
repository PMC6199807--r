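Package: haplometh
Title: Haplotype-Resolved Methylation Analysis of Long Bisulfite Amplicons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for targeted bisulfite amplicon sequencing
    with long (about 1.3 kbp) reads carrying dual 5-nt barcodes: demultiplexing,
    quality and bisulfite-conversion filtering, bisulfite-aware alignment to
    amplicon references, allele calling at amplicon-internal SNPs, per-haplotype
    CpG methylation quantification (allele-specific methylation), covariate
    residualisation and per-CpG testing with Benjamini-Hochberg adjustment,
    Boruta all-relevant CpG selection backed by a compact random forest, and
    stacked logistic prediction of smoking status from per-target models.
    Includes a fully parameterised synthetic cohort and bisulfite read
    simulator with truth tables for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
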