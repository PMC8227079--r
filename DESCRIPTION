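Package: mitescape
Title: Genome-Wide Annotation and Analysis of Miniature Inverted-Repeat
    Transposable Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the genome-wide landscape analysis of miniature
    inverted-repeat transposable elements (MITEs). Locates full-length
    copies of consensus MITE families in a genome under the 80-80-80
    similarity rule with end anchoring, calls terminal inverted repeats
    (TIRs) and target site duplications (TSDs) to classify copies into
    Class II superfamily groups (Stowaway, Tourist, hAT-like,
    Mutator-like, and microsatellite-associated MiMs), mines putative
    autonomous Mutator partners, clusters consensi into families,
    categorizes copies by genomic context relative to gene models with
    Pearson chi-squared enrichment, computes co-transcription statistics
    (normalized RPK and the MITE/gene expression ratio), and compares
    family libraries across species under a 60/60 identity-coverage
    criterion. A synthetic-data module generates genomes with planted
    copies, gene annotations, and read counts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    rtracklayer,
    dplyr,
    tidyr,
    purrr,
    tibble,
    stringr,
    readr,
    rlang,
    ggplot2,
    generics,
    igraph,
    yaml,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
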