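Package: tcrdyn
Title: TCR-Beta Repertoire Dynamics, Convergence Networks, and Survival Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing peripheral T-cell receptor beta-chain (TCR-beta)
    repertoires sampled before and shortly after immune checkpoint blockade.
    Reads clonotype tables (AIRR rearrangement TSV or a simple CSV dialect),
    applies sample-level quality control, computes repertoire clonality
    (normalised Shannon entropy) and TCR convergence frequency, derives paired
    pre/post-treatment ratios and group labels, builds per-patient amino-acid
    CDR3 similarity networks under a Levenshtein distance threshold with
    diameter summaries, and associates repertoire features with overall
    survival via Kaplan-Meier estimation, log-rank tests, and Cox
    proportional-hazards models with backward stepwise selection. A synthetic
    cohort generator with known ground truth supports end-to-end testing and
    power analysis without access to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    survival,
    tibble
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
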