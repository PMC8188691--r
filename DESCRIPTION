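Package: taxbench
Title: Benchmarking Toolkit for Metagenome Taxonomic Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking metagenome taxonomic classifiers on
    simulated communities. Builds rank-abundance community profiles under a
    power-law decay model, simulates truth-labelled single-end Illumina-like
    reads from reference genomes on a per-read basis, parses NCBI-style
    taxonomies and resolves multi-hit alignments by lowest common ancestor,
    runs ordered sequential classification (bacteria, viruses, eukaryotes in
    any order, with classified reads removed between steps), and scores runs
    against truth with species-level recall, precision, per-abundance-bin
    detection probability and depth-trend statistics. A fixture generator
    (toy taxonomy and toy genomes) and a built-in exact k-mer classifier let
    complete pipelines run without external binaries or reference downloads.
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
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
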