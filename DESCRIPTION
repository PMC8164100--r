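Package: rmdor
Title: Restricted Mean Duration of Response for Randomized Phase 2 Screening Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and inference for restricted mean duration of response
    (DOR) and its Q-TWiST partition into durations of complete response,
    partial response and stable disease, computed from right-censored
    progression-free survival data as areas between Kaplan-Meier curves.
    Includes the probability-of-being-in-response curve, ratio and difference
    treatment effects with bootstrap confidence intervals and permutation
    tests, a four-test battery (log-rank PFS, chi-squared ORR, RMST ratio of
    PFS, restricted mean duration ratios), a multi-state synthetic trial
    generator with presets emulating immune checkpoint inhibitor trial
    scenarios, and a resampling simulator of randomized phase 2 screening
    trials that tabulates power and type I error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    survival,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
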