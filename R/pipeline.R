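#' Run the full analysis pipeline and write a report bundle
#'
#' Wires the stages together: label queries, build per-(user, condition)
#' timelines, apply the cohort-size filter, compute per-condition and
#' aggregate pre-diagnosis statistics, the lag-rate correlation, the MSR
#' stratification, and the hospital-lag analysis; writes tab-separated
#' tables, a JSON summary, and a machine-readable run manifest to
#' `out_dir`. Per-stage counts are logged to stderr. Re-running with the
#' same inputs and parameters reproduces the tables byte for byte.
#'
#' @param log Query-log tibble (`user_id`, `timestamp` POSIXct, `text`), or
#'   a path to a TSV readable by [read_query_log()].
#' @param lex A `lexicon`.
#' @param out_dir Output directory (created if needed).
#' @param min_users Cohort-size threshold for [cohort_filter()] (default 75).
#' @param msr_threshold MSR cut point for [msr_stratify()] (default 2).
#' @param radii Window radii in days for [window_fractions()] (default 7, 14).
#' @param hospital_conditions Conditions for the hospital-lag analysis;
#'   default: all retained conditions.
#' @param strict Strict query-log ingestion when `log` is a path.
#' @return Invisibly, a list with `timelines`, `retained`, `stats`,
#'   `aggregate`, `lag_rate` (`spearman_cor` or `NULL`), `msr`
#'   (`msr_strata`), `hospital`, `histogram`, `windows`.
#' @export
run_pipeline <- function(log, lex, out_dir,
                         min_users = 75, msr_threshold = 2,
                         radii = c(7, 14), hospital_conditions = NULL,
                         strict = TRUE) {
  stopifnot(inherits(lex, "lexicon"))
  if (is.character(log) && length(log) == 1) {
    inform(paste0("[ingest] reading ", log))
    log <- read_query_log(log, strict = strict)
  }
  check_log_frame(log)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inform(paste0("[ingest] ", nrow(log), " queries from ",
                dplyr::n_distinct(log$user_id), " users"))

  labeled <- label_queries(log, lex)
  inform(paste0("[detect] ", sum(labeled$is_daq), " DAQs, ",
                sum(nzchar(labeled$symptom_hits)), " symptom-bearing queries, ",
                sum(labeled$is_hospital), " hospital queries"))
  out_labeled <- mutate(labeled,
                        timestamp = format(.data$timestamp,
                                           "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  readr::write_tsv(out_labeled, file.path(out_dir, "labeled_queries.tsv"),
                   progress = FALSE)

  tl <- build_timelines(log, lex)
  if (nrow(tl) == 0) abort("no DAQ users found")
  readr::write_tsv(flatten_timelines(tl), file.path(out_dir, "timelines.tsv"),
                   progress = FALSE)
  retained <- cohort_filter(tl, min_users)
  inform(paste0("[timelines] ", nrow(tl), " (user, condition) pairs; ",
                length(retained), " condition(s) pass the >=", min_users,
                "-user filter"))
  if (length(retained) == 0) abort("no condition passes the cohort filter")
  tl_kept <- filter(tl, .data$condition %in% retained)

  stats <- condition_stats(tl_kept)
  readr::write_tsv(stats, file.path(out_dir, "condition_stats.tsv"),
                   progress = FALSE)
  agg <- if (nrow(stats) >= 2) aggregate_stats(stats) else NULL
  lag_rate <- if (sum(!is.na(stats$median_lag_days)) >= 3) {
    lag_rate_correlation(stats)
  } else NULL
  msr <- msr_stratify(stats, lex, threshold = msr_threshold)

  hosp <- hospital_stats(tl_kept, conditions = hospital_conditions)
  readr::write_tsv(hosp, file.path(out_dir, "hospital_stats.tsv"),
                   progress = FALSE)
  hist <- lag_histogram(tl_kept, conditions = hospital_conditions)
  readr::write_tsv(hist, file.path(out_dir, "lag_histogram.tsv"),
                   progress = FALSE)
  windows <- if (sum(hist$n) > 0) {
    window_fractions(tl_kept, conditions = hospital_conditions, radii = radii)
  } else NULL

  summary <- list(
    retained_conditions = retained,
    aggregate = agg,
    lag_rate_correlation = if (!is.null(lag_rate)) tidy(lag_rate) else NULL,
    msr_strata = glance(msr),
    window_fractions = windows
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  manifest <- list(
    package = "prediag",
    version = as.character(utils::packageVersion("prediag")),
    parameters = list(min_users = min_users, msr_threshold = msr_threshold,
                      radii = radii,
                      hospital_conditions = hospital_conditions),
    inputs = list(n_queries = nrow(log),
                  n_users = dplyr::n_distinct(log$user_id),
                  n_conditions_lexicon = nrow(lex$conditions))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  inform(paste0("[report] written to ", out_dir))

  invisible(list(
    timelines = tl, retained = retained, stats = stats, aggregate = agg,
    lag_rate = lag_rate, msr = msr, hospital = hosp, histogram = hist,
    windows = windows
  ))
}
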