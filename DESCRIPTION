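Package: hapsweep
Title: Candidate-Gene Selection Scans, Haplotype Networks and Diversity
    Contrasts for Inbred Crop Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end population-genetics toolkit for candidate-gene
    studies in highly inbred crop panels such as rice. Translates coding
    SNPs to amino-acid markers, runs phenotype association with
    multidimensional-scaling stratification covariates and
    Benjamini-Hochberg false-discovery control, scans chromosomes for
    selective sweeps with the linkage-disequilibrium omega statistic,
    contrasts windowed nucleotide diversity (Tajima's pi) between a focal
    gene and its flanks, collapses region haplotypes into a minimum
    spanning network, and summarises per-sample haplotype scores and
    their modality. A calibrated synthetic-data generator emulates a
    structured panel (outgroup relatives, two wild ecotypes, two
    cultivated subspecies) carrying a single functional coding
    polymorphism swept in alternative lineages, so the whole pipeline is
    testable without external resequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    igraph,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
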