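Package: dupseq
Title: Duplex Sequencing Mutagenesis Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of duplex sequencing experiments for in
    vivo mutagenesis assessment. Generates synthetic reference panels and raw
    duplex read families with configurable mutation, damage and sequencing
    error processes; collapses read families into duplex consensus reads via
    unique molecular identifier (UMI) correction, quality trimming, cigar
    filtering and two-strand consensus calling; calls ultrarare variants from
    duplex pileups; and computes per-nucleotide mutant frequencies with exact
    Poisson confidence intervals, fold inductions, log-normal clonal-expansion
    classification, 6- and 96-class trinucleotide mutational spectra with
    context normalization, transcription-coupled strand-bias statistics, and
    cosine-distance hierarchical clustering of spectra against signature
    catalogs.
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
    jsonlite,
    purrr,
    rlang,
    readr,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    VariantAnnotation,
    BiocGenerics,
    optparse,
    knitr
Config/testthat/edition: 3
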