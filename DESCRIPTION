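Package: faerspv
Title: Pharmacovigilance Signal Detection on FAERS-Style Adverse Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pharmacovigilance pipeline for spontaneous
    adverse-event reporting databases distributed as FAERS-style quarterly
    ASCII tables. Reads and validates the six-table relational model (DEMO,
    DRUG, REAC, OUTC, INDI, THER), deduplicates reports by the FDA
    case-identifier rule, builds pediatric suspect-drug cohorts through a
    configurable inclusion funnel, and screens drug-event pairs with the
    reporting odds ratio (ROR) and its Wald 95% confidence interval under the
    standard signal criteria (at least three reports and a CI lower bound
    above one). Descriptive surfaces include baseline characteristics with
    most-severe-outcome selection, fatal-case drill-downs, subgroup tables
    with time-to-onset medians, co-occurrence profiles, and an under-8
    dental-staining analysis. A synthetic report generator with injected
    odds-ratio signals and planted duplicate clusters makes every stage
    testable without access to the full corpus.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    stringr,
    rlang,
    vctrs,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
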