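Package: poagcea
Title: Cost-Effectiveness Analysis of Preservative-Free Glaucoma
    Pharmacotherapy with Concomitant Dry Eye
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic pipeline for comparing preservative-free and
    preservative-containing topical glaucoma therapy in eyes with primary
    open-angle glaucoma and dry-eye disease. Provides per-eye cohort
    validation and summarisation, yearly pharmacotherapy costing with a
    payer/patient reimbursement split, a two-strategy decision tree with
    expected-value roll-back and a path-enumeration oracle, incremental
    cost-effectiveness ratios with dominance classification and WHO
    GDP-multiple verdicts, one-way deterministic sensitivity analysis with
    tornado ordering and sign-flip scanning, and a calibrated synthetic
    cohort generator so the full analysis runs without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
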