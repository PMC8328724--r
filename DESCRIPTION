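Package: pairedDEP
Title: Paired Fold-Change Deregulation Calling for Label-Free Plasma Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for label-free quantitative proteomics of
    paired (before/after) plasma samples: spike-in internal-standard
    normalization, technical-replicate collapsing, quantifiability,
    missingness and sequence-coverage filtering, per-animal paired log2
    fold changes, k-of-n deregulated-protein (DEP) calling with
    control-group exclusion, time-point set partitioning, per-protein
    summary tables, and hypergeometric over-representation analysis
    against user-supplied gene sets. Includes a synthetic-data generator
    with planted deregulations and intensity-dependent missingness so
    every stage is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
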