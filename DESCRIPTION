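Package: subgenomics
Title: Methylome Calling and Sub-Genome Dominance Analysis for
    Mesopolyploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the triplicated sub-genomes of
    mesopolyploid Brassica genomes: spike-in-calibrated binomial calling
    of methylated cytosines with Benjamini-Hochberg false discovery
    control, genome-wide and metagene methylation summaries, Tukey
    one-degree-of-freedom tests for sub-genome by tissue interaction on
    fully retained gene triplets, collinear anchor chaining and
    fractionation statistics, chi-square tests for gene-family
    expansion, and half-tetrad centromere mapping from progeny of
    first-division-restitution unreduced gametes.  A synthetic-data
    module generates every input with known ground truth so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    zoo,
    ape,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown,
    optparse
VignetteBuilder: knitr
Config/testthat/edition: 3
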