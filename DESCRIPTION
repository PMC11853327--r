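Package: rorsignal
Title: Reporting Odds Ratio Signal Detection for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Disproportionality analysis for spontaneous adverse drug reaction
    (ADR) reporting data in the style of EudraVigilance line listings. Classifies
    MedDRA preferred terms into drug-resistance and drug-ineffectiveness
    conditions, aggregates individual case safety reports (ICSRs) into per-drug
    count tables, computes descriptive reporting statistics and outcome
    breakdowns, and screens drug-versus-comparator 2x2 contingency tables with
    the reporting odds ratio (ROR), its Wald 95 percent confidence interval and
    the EMA minimum-report signal rule. Includes a seeded synthetic ICSR
    generator with an exact-count mode so every pipeline stage is testable
    without database access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    readr,
    jsonlite,
    rlang,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
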