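Package: tmabquant
Title: Quantitative Peptidomics with Multiplex TMAB Isotopic Labels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for label-based relative quantification of endogenous
    peptides (proteasome products) measured by LC-MS after multiplex
    labeling with isotopologues of the amine-reactive TMAB tag
    (D0/D3/D6/D9/D12). Detects isotope clusters and multiplex peak groups
    in centroided MS1 peak lists, computes capped run-relative peptide
    ratios against a reference condition, summarises conditions with
    Student's t-tests and fold-change categories, and analyses cleavage-site
    P1 residue preferences in source-protein coordinates. Includes a
    synthetic degradome and spectrum generator with ground truth so every
    stage of the pipeline can be exercised and validated without
    instrument data.
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
    ggplot2,
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
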