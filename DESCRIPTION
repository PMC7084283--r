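Package: prediag
Title: Pre-Diagnosis Symptom Search Analysis of Query Logs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infodemiology toolkit for measuring how often search-engine users
    query about the symptoms of a medical condition before they first state a
    formal diagnosis. Implements rule-based detection of diagnosis
    ascertainment queries (DAQs), lexicon-driven symptom and hospital query
    attribution on per-user timelines, per-condition pre-diagnosis query
    rates with macro and pooled aggregation, severity-rank stratification,
    hospital-query lag timing, a condition-symptom recognition survey design,
    a tie-aware Spearman rank correlation with exact small-sample p-values,
    and a seeded synthetic query-log generator so the full pipeline is
    testable without access to proprietary search logs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    stringr,
    rlang,
    readr,
    yaml,
    jsonlite,
    ggplot2,
    generics,
    withr,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
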