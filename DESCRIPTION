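Package: ampminer
Title: Antimicrobial Peptide Mining from De Novo Transcriptome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An in silico antimicrobial-peptide (AMP) discovery workflow for
    de novo transcriptome assemblies. Provides six-frame translation and open
    reading frame delineation with completeness classification, exact
    Smith-Waterman local alignment of AMP reference peptides against contigs
    and predicted proteins with a raw-score filter, signal-peptide cleavage
    calling, cysteine-spacing domain detection (WAP, Kazal, ALF disulfide
    loop), physicochemical AMP screening, family classification, candidate
    deduplication and reporting, and RPKM expression quantification with
    read-count tiering. A seeded synthetic-transcriptome generator with a
    machine-readable truth table supports download-free validation of the
    whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
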