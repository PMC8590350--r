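Package: adrburden
Title: Economic Burden of Serious Post-Market Adverse Drug Reactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A pipeline for estimating the real-world economic burden of
    serious adverse drug reactions (ADRs) from spontaneous pharmacovigilance
    report extracts. Reads and deduplicates Canada Vigilance-style report
    tables, filters cohorts by drug name and reporting period, estimates
    exposure-normalized ADR outcome rates from drug sales, pools randomized
    controlled trial adverse-event proportions with a self-implemented
    DerSimonian-Laird random-effects meta-analysis, and computes the annual
    cost of serious ADRs from patient (human-capital), health-system
    (direct cost), and societal (friction-cost) perspectives, with
    deterministic base-case, one-way, and Monte Carlo probabilistic
    sensitivity analyses. Includes a synthetic report generator with a
    closed-form cost oracle for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
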