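#' Plot per-condition pre-diagnosis query rates
#'
#' Horizontal bar chart of the percentage of DAQ users who queried a
#' relevant symptom before their first DAQ, ordered by rate.
#'
#' @param stats Output of [condition_stats()] (or
#'   [reference_condition_counts()]).
#' @return A ggplot object.
#' @export
plot_condition_rates <- function(stats) {
  ggplot2::ggplot(
    stats,
    ggplot2::aes(x = .data$pct_before,
                 y = stats::reorder(.data$condition, .data$pct_before))
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "users querying symptoms before first DAQ (%)",
      y = NULL,
      title = "Pre-diagnosis symptom-query rate by condition"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the hospital-to-DAQ lag histogram
#'
#' Distribution of whole-day offsets between each user's first hospital
#' query and their first DAQ; negative offsets mean the hospital query came
#' first.
#'
#' @param hist Output of [lag_histogram()].
#' @return A ggplot object.
#' @export
plot_lag_histogram <- function(hist) {
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$day_offset, y = .data$n)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(
      x = "days from first DAQ to first hospital query",
      y = "users",
      title = "Timing of first hospital query relative to first DAQ"
    ) +
    ggplot2::theme_minimal()
}

#' Severity-stratum rate plot
#' @param object An `msr_strata` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot msr_strata
#' @export
autoplot.msr_strata <- function(object, ...) {
  df <- tibble(
    stratum = factor(
      c(sprintf("MSR <= %d", object$threshold),
        sprintf("MSR > %d", object$threshold)),
      levels = c(sprintf("MSR <= %d", object$threshold),
                 sprintf("MSR > %d", object$threshold))
    ),
    rate = c(object$rate_low_pct, object$rate_high_pct)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stratum, y = .data$rate)) +
    ggplot2::geom_col(fill = c("firebrick", "grey60")) +
    ggplot2::labs(
      x = NULL, y = "pre-diagnosis query rate (%)",
      title = "Query rates by symptom severity stratum"
    ) +
    ggplot2::theme_minimal()
}

#' Per-condition recognition plot
#' @param object A `survey_summary` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot survey_summary
#' @export
autoplot.survey_summary <- function(object, ...) {
  ggplot2::ggplot(
    object$by_condition,
    ggplot2::aes(x = .data$recognition_pct,
                 y = stats::reorder(.data$condition, .data$recognition_pct))
  ) +
    ggplot2::geom_col(fill = "darkseagreen4") +
    ggplot2::labs(
      x = "responses recognizing the condition (%)", y = NULL,
      title = "Condition recognition in the survey"
    ) +
    ggplot2::theme_minimal()
}
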