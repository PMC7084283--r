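#' Build per-(user, condition) timelines from a query log
#'
#' Reduces a raw query stream to one row per (user, condition) pair for
#' which the user issued at least one DAQ for that condition. For each pair
#' it records the first DAQ time, the first symptom-query time (minimum over
#' the user's entire record, before or after the DAQ), whether the first
#' symptom query strictly preceded the first DAQ, per-symptom query counts,
#' and the user's first hospital/clinic query time (over the whole record,
#' condition-independent).
#'
#' "Before" is strict inequality at second resolution: a symptom mention in
#' the same query (same timestamp) as the first DAQ does not count as a
#' pre-diagnosis symptom query.
#'
#' @param log Tibble with columns `user_id`, `timestamp` (POSIXct), `text`.
#' @param lex A `lexicon`.
#' @return Tibble sorted by (condition, user_id) with columns `user_id`,
#'   `condition`, `t_first_daq`, `t_first_symptom` (`NA` when the user never
#'   queried a symptom of the condition), `symptom_before_daq` (logical),
#'   `symptom_query_count`, `symptom_counts` (list-column of per-symptom
#'   tibbles with `symptom`, `n`, `t_first`), and `t_first_hospital`.
#' @export
build_timelines <- function(log, lex) {
  check_log_frame(log)
  if (!inherits(log$timestamp, "POSIXct")) {
    abort("`log$timestamp` must be POSIXct; see read_query_log().")
  }
  daq <- daq_hits(log, lex)
  if (nrow(daq) == 0) {
    return(tibble(
      user_id = character(), condition = character(),
      t_first_daq = log$timestamp[0], t_first_symptom = log$timestamp[0],
      symptom_before_daq = logical(), symptom_query_count = integer(),
      symptom_counts = list(), t_first_hospital = log$timestamp[0]
    ))
  }
  first_daq <- daq %>%
    group_by(.data$user_id, .data$condition) %>%
    summarise(t_first_daq = min(.data$timestamp), .groups = "drop")

  sym <- symptom_hits(log, lex)
  if (nrow(sym) == 0) {
    per_symptom <- tibble(user_id = character(), condition = character(),
                          symptom = character(), n = integer(),
                          t_first = log$timestamp[0])
  } else {
    per_symptom <- sym %>%
      group_by(.data$user_id, .data$condition, .data$symptom) %>%
      summarise(n = n(), t_first = min(.data$timestamp), .groups = "drop")
  }
  if (nrow(per_symptom) == 0) {
    sym_summary <- tibble(user_id = character(), condition = character(),
                          t_first_symptom = log$timestamp[0],
                          symptom_query_count = integer())
  } else {
    sym_summary <- per_symptom %>%
      group_by(.data$user_id, .data$condition) %>%
      summarise(
        t_first_symptom = min(.data$t_first),
        symptom_query_count = sum(.data$n),
        .groups = "drop"
      )
  }
  sym_nested <- tidyr::nest(per_symptom,
                            symptom_counts = c("symptom", "n", "t_first"))

  hh <- hospital_hits(log, lex)
  if (nrow(hh) == 0) {
    hosp <- tibble(user_id = character(), t_first_hospital = log$timestamp[0])
  } else {
    hosp <- hh %>%
      group_by(.data$user_id) %>%
      summarise(t_first_hospital = min(.data$timestamp), .groups = "drop")
  }

  out <- first_daq %>%
    left_join(sym_summary, by = c("user_id", "condition")) %>%
    left_join(sym_nested, by = c("user_id", "condition")) %>%
    left_join(hosp, by = "user_id") %>%
    mutate(
      symptom_query_count = dplyr::coalesce(.data$symptom_query_count, 0L),
      symptom_before_daq = !is.na(.data$t_first_symptom) &
        .data$t_first_symptom < .data$t_first_daq
    ) %>%
    select("user_id", "condition", "t_first_daq", "t_first_symptom",
           "symptom_before_daq", "symptom_query_count", "symptom_counts",
           "t_first_hospital") %>%
    arrange(.data$condition, .data$user_id)
  out
}

#' Retain conditions with a large enough self-identified cohort
#'
#' Conditions are kept when at least `min_users` distinct users issued a DAQ
#' for them. The default of 75 is the cohort-size threshold used to ensure
#' statistical power; scale it down together with synthetic cohort sizes.
#'
#' @param timelines Output of [build_timelines()].
#' @param min_users Minimum distinct DAQ users per condition (default 75).
#' @return Sorted character vector of retained condition names.
#' @export
cohort_filter <- function(timelines, min_users = 75) {
  stopifnot(min_users >= 1)
  if (nrow(timelines) == 0) return(character(0))
  timelines %>%
    group_by(.data$condition) %>%
    summarise(n_users = n_distinct(.data$user_id), .groups = "drop") %>%
    filter(.data$n_users >= min_users) %>%
    pull("condition") %>%
    sort()
}

#' Mean number of queries per queried symptom
#'
#' Pools all (user, condition, symptom) triples with at least one query and
#' averages their counts: "how many times does a user ask about a symptom
#' they ask about at all?". Counts include queries issued after the DAQ.
#'
#' @param timelines Output of [build_timelines()].
#' @return A single number, or `NA` when no symptom was ever queried.
#' @export
mean_symptom_queries <- function(timelines) {
  if (nrow(timelines) == 0) return(NA_real_)
  counts <- timelines %>%
    filter(!vapply(.data$symptom_counts, is.null, logical(1))) %>%
    tidyr::unnest("symptom_counts")
  if (nrow(counts) == 0) return(NA_real_)
  mean(counts$n)
}
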