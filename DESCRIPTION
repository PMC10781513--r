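Package: recland
Title: Recombination Landscape Analysis for LD-Based Genetic Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for downstream analysis of linkage-disequilibrium-based
    recombination maps in avian-like genomes. Converts piecewise-constant
    per-generation recombination rates into genetic-map units (cM/Mb),
    computes windowed and per-chromosome summaries, associates recombination
    with genomic features (GC content, CpG islands, genes, nucleotide
    diversity, sequence uniqueness, retrotransposon families) through
    Kendall rank and partial rank correlations, profiles rates around
    anchors such as transcription start sites and CpG islands, and
    quantifies cross-species conservation of recombination landscapes.
    Includes a seed-controlled synthetic-data generator with known ground
    truth for validating every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    IRanges,
    S4Vectors,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
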