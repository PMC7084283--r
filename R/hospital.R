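# Signed lag in fractional days between first hospital query and first DAQ;
# negative = hospital query came first.
hospital_lag_frame <- function(timelines, conditions = NULL) {
  if (!is.null(conditions)) {
    timelines <- filter(timelines, .data$condition %in% conditions)
  }
  mutate(timelines,
         lag_days = as.numeric(difftime(.data$t_first_hospital,
                                        .data$t_first_daq, units = "days")))
}

#' Hospital-query timing statistics per condition
#'
#' For each condition: how many DAQ users ever queried for a hospital,
#' medical center or clinic; how many of those made their first hospital
#' query before their first DAQ (signed lag < 0); and the median absolute
#' lag in days. A tight lag distribution indicates that DAQs are issued
#' around the time of actual diagnosis.
#'
#' @param timelines Output of [build_timelines()].
#' @param conditions Optional restriction to a set of conditions (the
#'   analysis is most meaningful for conditions, such as cancers, where a
#'   hospital visit closely follows diagnosis).
#' @return Tibble: `condition`, `n_total`, `n_with_hospital`,
#'   `pct_with_hospital`, `n_hospital_before_daq`,
#'   `pct_hospital_before_daq`, `median_abs_lag_days`. Percentages are
#'   unrounded.
#' @export
hospital_stats <- function(timelines, conditions = NULL) {
  hl <- hospital_lag_frame(timelines, conditions)
  if (nrow(hl) == 0) abort("No timelines for the requested conditions.")
  hl %>%
    group_by(.data$condition) %>%
    summarise(
      n_total = n(),
      n_with_hospital = sum(!is.na(.data$lag_days)),
      pct_with_hospital = 100 * .data$n_with_hospital / .data$n_total,
      n_hospital_before_daq = sum(.data$lag_days < 0, na.rm = TRUE),
      pct_hospital_before_daq =
        100 * .data$n_hospital_before_daq / .data$n_with_hospital,
      median_abs_lag_days = if (any(!is.na(.data$lag_days))) {
        median(abs(.data$lag_days[!is.na(.data$lag_days)]))
      } else NA_real_,
      .groups = "drop"
    ) %>%
    arrange(.data$condition)
}

#' Whole-day histogram of signed hospital-to-DAQ lags
#'
#' Bins the signed lag (first hospital query minus first DAQ; negative means
#' the hospital query came first) at whole-day resolution (`floor(lag)`),
#' one count per hospital-querying user. Counts sum to the number of users
#' with a hospital query.
#'
#' @inheritParams hospital_stats
#' @return Tibble `day_offset`, `n` (only non-empty bins), sorted by offset.
#' @export
lag_histogram <- function(timelines, conditions = NULL) {
  hl <- hospital_lag_frame(timelines, conditions)
  lags <- hl$lag_days[!is.na(hl$lag_days)]
  if (length(lags) == 0) {
    return(tibble(day_offset = integer(), n = integer()))
  }
  tibble(day_offset = as.integer(floor(lags))) %>%
    count(.data$day_offset) %>%
    arrange(.data$day_offset)
}

#' Fraction of hospital queries within symmetric windows around the DAQ
#'
#' Pooled over the given conditions, computes for each radius `w` the
#' fraction of hospital-querying users whose absolute signed lag is at most
#' `w` days, plus the fraction whose first hospital query fell on the same
#' calendar date as their first DAQ. Fractions are monotone non-decreasing
#' in the radius.
#'
#' @inheritParams hospital_stats
#' @param radii Positive day radii (default `c(7, 14)`, i.e. "within a week
#'   / two weeks before or after the DAQ").
#' @return Tibble `metric`, `radius_days`, `fraction`, `n_users`. When no
#'   user queried a hospital the fractions are `NA` and a warning is issued.
#' @export
window_fractions <- function(timelines, conditions = NULL, radii = c(7, 14)) {
  stopifnot(length(radii) >= 1, all(radii > 0))
  hl <- hospital_lag_frame(timelines, conditions) %>%
    filter(!is.na(.data$lag_days))
  n_users <- nrow(hl)
  if (n_users == 0) {
    warn("No hospital-querying users; window fractions undefined.")
    return(tibble(
      metric = c(sprintf("within_%gd", radii), "same_day"),
      radius_days = c(radii, NA_real_),
      fraction = NA_real_, n_users = 0L
    ))
  }
  fracs <- vapply(radii, function(w) mean(abs(hl$lag_days) <= w), numeric(1))
  same_day <- mean(as.Date(hl$t_first_hospital, tz = "UTC") ==
                     as.Date(hl$t_first_daq, tz = "UTC"))
  tibble(
    metric = c(sprintf("within_%gd", radii), "same_day"),
    radius_days = c(radii, NA_real_),
    fraction = c(fracs, same_day),
    n_users = n_users
  )
}
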