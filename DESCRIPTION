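Package: panforge
Title: Bacterial Pan-Genome Construction, Rarefaction and Phylogenomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds bacterial pan-genomes from per-genome protein sets:
    all-vs-all protein similarity under identity/coverage/e-value thresholds,
    single-linkage ortholog families, core/accessory/strain-specific
    partitioning, pan- and core-genome rarefaction with Heaps'-law and
    exponential-decay fits (open/closed classification), fragment-based
    average nucleotide identity (ANIb-style) with species delineation at the
    95% rule, and a neighbor-joining phylogeny from single-copy core genes.
    Includes a synthetic pan-genome simulator with known family structure and
    nucleotide divergence so every stage is verifiable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    ape,
    data.table,
    igraph,
    minpack.lm,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    phangorn,
    withr
Config/testthat/edition: 3
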