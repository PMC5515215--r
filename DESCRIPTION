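Package: quorumflow
Title: Quorum Sensing and Quenching Analysis for Activated Sludge Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying community-level quorum sensing (QS) and quorum
    quenching (QQ) in floccular and granular activated sludge. Implements fast
    16S rRNA V6 tag profiling of sequencing reads via degenerate-primer
    scanning, estimation of N-acyl homoserine lactone (AHL) degradation
    kinetics and half-lives under zero- and first-order models, LC-MS/MS-style
    quantification with matrix-matched calibration, detection and
    quantification limits and identity confirmation, isolate QS/QQ phenotype
    classification, and correlation analysis between community member
    abundances and AHL concentration profiles with false-discovery-rate
    control and hierarchical clustering. Seeded synthetic-data generators with
    ground truth make every stage testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
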