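#' Bundled reference counts from an archival search-log study
#'
#' Per-condition counts observed in a year-long archival analysis of US
#' English web-search logs (May 2017 - April 2018), bundled as plain-text
#' tables under `inst/extdata/`. They serve two purposes: reproducing the
#' study-level aggregates arithmetically, and parameterizing
#' [scenario_reference()] so synthetic cohorts mirror realistic sizes and
#' rates.
#'
#' * `reference_condition_counts()`: for each of 20 conditions, the number
#'   of self-identified (DAQ-issuing) users `n_total`, the number who
#'   queried a relevant symptom before their first DAQ `n_before`, and the
#'   reported percentage `pct_before` (kept as printed; for a few rows the
#'   printed percentage differs slightly from `100 * n_before / n_total`).
#' * `reference_hospital_counts()`: for the 3 malignant conditions, the
#'   median hospital-to-DAQ lag in days, hospital-querying user counts, and
#'   how many queried a hospital before the DAQ.
#' * `reference_msr_strata()`: pooled counts and reported rates for the
#'   strata of conditions with minimum symptom MSR <= 2 versus > 2.
#' * `reference_survey_counts()`: response totals of the recognition survey.
#'
#' @return A tibble (see above).
#' @export
reference_condition_counts <- function() {
  readr::read_tsv(
    system.file("extdata", "reference_condition_counts.tsv",
                package = "prediag", mustWork = TRUE),
    col_types = "ciid", progress = FALSE
  )
}

#' @rdname reference_condition_counts
#' @export
reference_hospital_counts <- function() {
  readr::read_tsv(
    system.file("extdata", "reference_hospital_counts.tsv",
                package = "prediag", mustWork = TRUE),
    col_types = "cdiii", progress = FALSE
  )
}

#' @rdname reference_condition_counts
#' @export
reference_msr_strata <- function() {
  readr::read_tsv(
    system.file("extdata", "reference_msr_strata.tsv",
                package = "prediag", mustWork = TRUE),
    col_types = "ciid", progress = FALSE
  )
}

#' @rdname reference_condition_counts
#' @export
reference_survey_counts <- function() {
  readr::read_tsv(
    system.file("extdata", "reference_survey_counts.tsv",
                package = "prediag", mustWork = TRUE),
    col_types = "iid", progress = FALSE
  )
}
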