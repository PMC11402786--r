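Package: essplice
Title: Exon-Skipping Splicing Quantification and Heterogeneity Analysis from
    Targeted Amplicon Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies exon-skipping splicing (ESS) isoforms from targeted
    amplicon sequencing (SPAR-seq style) read data: merges paired-end reads,
    routes unmergeable long-amplicon pairs, classifies reads against an
    isoform catalog by edit distance, and computes length-normalized
    splicing percentages per sample.  Summarises single-blastomere splicing
    heterogeneity within embryos (spike-in normalisation, relative levels,
    spatial-group t and chi-squared tests) and compares RNA secondary
    structures between fragmented transcripts via a maximum-pairing folder,
    an ordered tree-edit dissimilarity on bracket structures, and an
    empirical-null quantile threshold.  Ships a synthetic-data generator
    that emulates the full study design for validation.
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
    ggplot2,
    jsonlite,
    methods,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
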