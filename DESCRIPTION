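Package: tumorgri
Title: Growth-Rate Inhibition and Combination Synergy Analysis for
    Preclinical In Vivo Efficacy Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for caliper-based preclinical (syngeneic or
    xenograft) tumor efficacy studies. Fits each animal's tumor-volume series
    to an exponential growth model by log-linear least squares, summarizes
    per-arm mean growth rates, and computes the growth-rate-inhibition (GRI)
    statistic with a Welch two-sample test. For four-arm combination designs
    it computes a growth-rate synergy score with error propagation across
    arms, Welch-Satterthwaite degrees of freedom, a two-tailed t-test, and a
    synergistic/additive/sub-additive/antagonistic classification. Also
    provides surrogate-endpoint Kaplan-Meier and log-rank survival analysis
    at a tumor-volume threshold, body-weight-loss and complete-responder
    summaries, study report export, and a seeded synthetic-cohort simulator
    with known ground truth for end-to-end validation and Monte-Carlo
    operating-characteristic studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
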