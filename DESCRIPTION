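Package: survcare
Title: Guideline-Adherence Quality Indicators for Breast Cancer Survivorship Care
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds censored survivorship cohorts from linked registry and
    claims event tables and classifies each patient-year against
    guideline-based quality-of-care indicators for breast cancer survivors:
    physician visit frequency (measured three ways), surveillance breast
    imaging under a 330-day interval rule or a program-flag rule,
    non-recommended imaging for metastatic disease, chronic-disease visit
    indicators, and preventive-care indicators. Includes the Usual Provider
    of Care (UPC) continuity index with its four-level categorization, a
    descriptive reporting layer, and a fully parameterized synthetic-claims
    generator with a truth table so every stage is testable without access
    to confidential administrative databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
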