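Package: faersignal
Title: Disproportionality Signal Detection and Time-to-Onset Analysis for
    FAERS Spontaneous Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for pharmacovigilance analysis of FDA Adverse Event
    Reporting System (FAERS) quarterly ASCII extracts: reading the
    dollar-delimited DEMO/DRUG/REAC/THER/OUTC tables, deduplicating report
    versions by the FDA rule (latest FDA receipt date per case, ties to the
    higher PRIMARYID), extracting a primary-suspect drug cohort, mapping
    MedDRA Preferred Terms to System Organ Classes through a user-supplied
    dictionary, computing reporting odds ratios with 95% confidence
    intervals at PT and SOC level, sex and age subgroup analysis,
    time-to-onset summaries with Kruskal-Wallis comparisons, and Weibull
    shape-based failure-type classification. Includes a synthetic FAERS-like
    data generator with planted odds-ratio signals and planted Weibull onset
    distributions so the full pipeline is testable without database access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    rlang,
    Rcpp,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    fitdistrplus,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
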