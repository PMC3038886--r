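Package: localminimax
Title: Individualized Tumor Classification by Local Minimax Kernel Learning
Version: 0.1.0
Authors@R: person("Lowell", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Two-stage individualized classifier for binary tumor/normal
    calls from gene expression profiles. Feature selection uses the
    k-Top-Scoring-Pairs (k-TSP) algorithm; per-patient prediction uses a
    local minimax kernel estimator (the contextual Tikhonov estimator on
    an optimally chosen neighborhood) that returns, for each queried
    patient, a probability-of-cancer estimate, a finite-sample bound on
    its mean squared error, a one-sided 90 percent confidence interval,
    and a confident-predictability decision with a reject option.
    Includes leave-one-out cross-validation drivers, a 3-nearest-neighbor
    baseline, synthetic-data generators for end-to-end and coverage
    validation, and readers for delimited and GCT expression matrices.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
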