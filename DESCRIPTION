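Package: zcdtools
Title: Detection and Comparative Analysis of the P2X7 Ballast
    Zn-Coordinating Cysteine Domain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative analysis of the P2X7 receptor
    C-terminal "ballast" region and its conserved core, the
    Zn-coordinating cysteine-based domain (ZCD). Compiles the
    consensus-pattern notation used to describe the three ordered
    cysteine clusters, scans protein sequences for them, annotates
    companion features (C-cys anchor, GDP-binding residues, LPS-like
    and beta-arrestin motifs, loss-of-function polymorphism sites),
    and classifies domain architectures into P2X7-like, nanor-like
    and other ZCD-bearing proteins. Includes motif-anchored
    alignment, maximum-likelihood JTT distances, neighbor-joining
    tree reconstruction with bootstrap support, five-marker
    synteny-window comparison, and seeded synthetic-data generators
    (planted ZCD proteins, sequence families evolved along a tree,
    gene neighborhoods with shared markers) for validation.
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
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
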