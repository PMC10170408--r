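Package: tcrconverge
Title: Clonality and Sequence-Convergence Analysis of TCR-Beta Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for bulk T-cell receptor beta-chain (CDR3)
    repertoire sequencing of solid-tumour samples. Reads immunoSEQ-style
    rearrangement files, quantifies per-sample T-cell fractions from
    template counts and input DNA mass, profiles repertoire clonality with
    Hill diversity and evenness curves, builds Levenshtein-distance-1
    sequence-convergence networks with discrete power-law goodness-of-fit
    diagnostics and public/private clonotype stratification, and measures
    pairwise repertoire overlap with the Morisita-Horn index. Includes a
    synthetic cohort generator with planted ground truth so that every
    stage of the pipeline can be validated without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    dplyr,
    igraph,
    Matrix,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
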