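Package: cldrisk
Title: Case-Control Suicide Risk Modelling from Routine Health Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Feasibility-style analysis of suicide risk estimation from
    routinely collected electronic health records. Provides a synthetic
    matched case-control cohort simulator (20 controls per case, matched on
    sex and week of birth), time-windowed binary feature encoding anchored
    on an index contact date, shallow feed-forward neural networks trained
    from first principles with an imbalance-weighted regularized
    squared-error cost, pair-preserving repeated k-fold cross-validation
    with a corrected resampled t-test and false discovery rate adjustment,
    a label-shuffle null experiment, and model-behaviour analyses based on
    single-factor toggling of the input bits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
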