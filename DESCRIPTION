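Package: survscreen
Title: Screening Gene-Gene Interactions in High-Dimensional Survival Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and evaluates two-way interaction effects in
    high-dimensional right-censored survival data. Combines componentwise
    likelihood-based boosting for the Cox proportional hazards model with
    random survival forests (log-rank splitting, Nelson-Aalen terminal
    estimates, permutation importance) to pre-select candidate interaction
    pairs, optionally after orthogonalizing covariates against detected
    main effects. Final models are assessed by inverse-probability-of-
    censoring-weighted Brier score curves and integrated prediction error
    relative to the Kaplan-Meier estimator. Includes a simulation engine
    for block-correlated covariates with exponential event and censoring
    times and scoring of selection sensitivity across replicates.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    data.table,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
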