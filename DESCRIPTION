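Package: mitescout
Title: Discovery and Characterization of Miniature Inverted-Repeat
    Transposable Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A workflow for characterizing miniature inverted-repeat
    transposable elements (MITEs) in plant genome assemblies: de novo
    detection of candidates bounded by terminal inverted repeats (TIRs) and
    target site duplications (TSDs), clustering of candidates into families
    with consensus sequences and TSD-based superfamily classification,
    copy-number estimation both from assemblies (intact-copy counting) and
    from whole-genome-shotgun read depth normalized to haploid coverage,
    classification of insertions relative to gene models, insertion-age
    dating from Kimura two-parameter divergence to a family consensus,
    neighbor-joining phylogenies with bootstrap support, and in-silico
    typing of insertion-site polymorphism across assemblies. A synthetic
    data module generates genomes with planted elements of known age so
    every stage can be validated against a truth table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    GenomicRanges,
    ggplot2,
    generics,
    IRanges,
    purrr,
    Rcpp,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
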