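Package: vigicomplete
Title: Completeness Scoring of Adverse Drug Reaction Line Listings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the Vigi4Eudra completeness score, an adaptation of the
    vigiGrade completeness score to tabular line listings exported from the
    EudraVigilance adverse drug reaction database. Reads csv/xlsx line
    listings with keyword-based column resolution, expands reports into
    ADR-drug combinations, applies the ten-category multiplicative penalty
    scheme, and aggregates per-report mean and best scores with dataset
    summaries. Includes a seeded synthetic line-listing generator with known
    ground truth, score comparison against a reference score set with
    intraclass correlation (two-way random effects, absolute agreement) and
    deviation flagging, and category-level discrepancy attribution at report
    and ADR-drug level.
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
    purrr,
    readr,
    readxl,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
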