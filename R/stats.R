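#' Per-condition pre-diagnosis symptom-query statistics
#'
#' For each condition (optionally restricted to a retained cohort), counts
#' the DAQ users (`n_total`), the users whose first relevant symptom query
#' strictly preceded their first DAQ (`n_before`), the percentage
#' `100 * n_before / n_total` (reported to 2 decimals), and the median
#' symptom-to-DAQ lead time in fractional days over the pre-diagnosis
#' searchers (midpoint of the middle two for even counts).
#'
#' @param timelines Output of [build_timelines()].
#' @param conditions Optional character vector restricting the conditions
#'   (e.g. the output of [cohort_filter()]); default: all present.
#' @return Tibble with columns `condition`, `n_before`, `n_total`,
#'   `pct_before`, `median_lag_days` (`NA` when no user searched before).
#' @export
condition_stats <- function(timelines, conditions = NULL) {
  if (!is.null(conditions)) {
    timelines <- filter(timelines, .data$condition %in% conditions)
  }
  if (nrow(timelines) == 0) abort("No timelines for the requested conditions.")
  timelines %>%
    mutate(lag_days = as.numeric(difftime(.data$t_first_daq,
                                          .data$t_first_symptom,
                                          units = "days"))) %>%
    group_by(.data$condition) %>%
    summarise(
      n_before = sum(.data$symptom_before_daq),
      n_total = n(),
      pct_before = round(100 * .data$n_before / .data$n_total, 2),
      median_lag_days = if (any(.data$symptom_before_daq)) {
        median(.data$lag_days[.data$symptom_before_daq])
      } else NA_real_,
      .groups = "drop"
    ) %>%
    arrange(.data$condition)
}

#' Aggregate per-condition rates into study-level summaries
#'
#' Two aggregations are exposed side by side because they answer different
#' questions: the macro (unweighted) mean and sample standard deviation of
#' the per-condition percentages treat every condition equally, while the
#' pooled ratio (summed numerators over summed denominators) weights by
#' cohort size. Cohort-size dispersion is summarised as the mean and its
#' standard error (sample SD / sqrt(k)) over the k conditions.
#'
#' @param stats Tibble with columns `pct_before` and `n_total` (and,
#'   optionally, `n_before` for the pooled counts), e.g. from
#'   [condition_stats()] or [reference_condition_counts()].
#' @return One-row tibble: `k_conditions`, `macro_mean_pct`, `macro_sd_pct`,
#'   `pooled_n_before`, `pooled_n_total`, `pooled_pct`, `mean_cohort_size`,
#'   `se_cohort_size`.
#' @export
aggregate_stats <- function(stats) {
  need <- c("pct_before", "n_total")
  miss <- setdiff(need, names(stats))
  if (length(miss) > 0) {
    abort(paste0("`stats` is missing column(s): ", paste(miss, collapse = ", ")))
  }
  k <- nrow(stats)
  if (k < 2) abort("Need at least 2 conditions (SD undefined otherwise).")
  has_counts <- "n_before" %in% names(stats)
  pooled_n_before <- if (has_counts) sum(stats$n_before) else NA_integer_
  pooled_n_total <- sum(stats$n_total)
  tibble(
    k_conditions = k,
    macro_mean_pct = mean(stats$pct_before),
    macro_sd_pct = sd(stats$pct_before),
    pooled_n_before = pooled_n_before,
    pooled_n_total = pooled_n_total,
    pooled_pct = 100 * pooled_n_before / pooled_n_total,
    mean_cohort_size = mean(stats$n_total),
    se_cohort_size = sd(stats$n_total) / sqrt(k)
  )
}

#' Correlation between pre-diagnosis rate and symptom-to-DAQ lead time
#'
#' Spearman correlation, across conditions, between the percentage of users
#' who searched their symptoms before the DAQ and the median number of days
#' between first symptom query and DAQ. A positive coefficient means
#' conditions with longer symptomatic lead time are queried about more often
#' before diagnosis. Conditions with no pre-diagnosis searcher carry no
#' median lag and are dropped with a warning.
#'
#' @param stats Output of [condition_stats()].
#' @param ... Passed to [spearman_cor()].
#' @return A `spearman_cor` object.
#' @export
lag_rate_correlation <- function(stats, ...) {
  keep <- !is.na(stats$median_lag_days) & !is.na(stats$pct_before)
  if (any(!keep)) {
    warn(paste0(sum(!keep), " condition(s) without a median lag dropped ",
                "from the lag-rate correlation."))
  }
  stats <- stats[keep, ]
  spearman_cor(stats$pct_before, stats$median_lag_days, ...)
}

#' Percent increase of one rate over another
#'
#' `100 * (rate_low_msr - rate_high_msr) / rate_high_msr`: how much more
#' often users query before diagnosis for conditions with more worrying
#' symptoms. Returned unrounded; round to the nearest integer for reporting.
#'
#' @param rate_low_msr,rate_high_msr Percentage rates for the more-worrying
#'   (low MSR) and less-worrying (high MSR) strata.
#' @return A single number.
#' @examples
#' round(pct_increase(19.13, 16.81))  # 14
#' @export
pct_increase <- function(rate_low_msr, rate_high_msr) {
  100 * (rate_low_msr - rate_high_msr) / rate_high_msr
}

#' Stratify conditions by minimum Medical Severity Rank
#'
#' Splits conditions into a "worrying" stratum (minimum symptom MSR at or
#' below `threshold`; MSR 1 = most urgent) and a less worrying stratum
#' (minimum MSR above it); conditions with no ranked symptom are excluded.
#' Stratum rates are pooled by default (summed numerators over summed
#' denominators, as a percentage) with a macro-mean option, and the percent
#' increase of the low-MSR over the high-MSR rate is reported. An empty
#' stratum flags the comparison instead of erroring.
#'
#' @param stats Output of [condition_stats()].
#' @param lex A `lexicon` supplying per-symptom MSRs.
#' @param threshold MSR cut point in 1..10 (default 2).
#' @param rates `"pooled"` (default) or `"macro"`.
#' @return An object of class `msr_strata`: list with `threshold`, `rates`,
#'   `membership` (tibble `condition`, `min_msr`, `group`), `rate_low_pct`,
#'   `rate_high_pct`, `pct_increase`, `pct_increase_rounded`, `flagged`.
#' @export
msr_stratify <- function(stats, lex, threshold = 2, rates = c("pooled", "macro")) {
  rates <- match.arg(rates)
  if (!(threshold >= 1 && threshold <= 10)) abort("`threshold` must be in 1..10.")
  mm <- min_msr(lex)
  membership <- stats %>%
    left_join(mm, by = "condition") %>%
    mutate(group = dplyr::case_when(
      is.na(.data$min_msr) ~ "excluded",
      .data$min_msr <= threshold ~ "low_msr",
      TRUE ~ "high_msr"
    ))
  stratum_rate <- function(g) {
    rows <- filter(membership, .data$group == g)
    if (nrow(rows) == 0) return(NA_real_)
    if (rates == "pooled") 100 * sum(rows$n_before) / sum(rows$n_total)
    else mean(rows$pct_before)
  }
  rate_low <- stratum_rate("low_msr")
  rate_high <- stratum_rate("high_msr")
  flagged <- is.na(rate_low) || is.na(rate_high) ||
    (!is.na(rate_high) && rate_high == 0)
  inc <- if (flagged) NA_real_ else pct_increase(rate_low, rate_high)
  structure(
    list(
      threshold = threshold,
      rates = rates,
      membership = select(membership, "condition", "min_msr", "group",
                          "n_before", "n_total", "pct_before"),
      rate_low_pct = rate_low,
      rate_high_pct = rate_high,
      pct_increase = inc,
      pct_increase_rounded = if (is.na(inc)) NA_real_ else round(inc),
      flagged = flagged
    ),
    class = "msr_strata"
  )
}

#' @export
print.msr_strata <- function(x, ...) {
  cat("MSR stratification (threshold ", x$threshold, ", ", x$rates,
      " rates)\n", sep = "")
  tab <- table(x$membership$group)
  cat("  conditions: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  if (x$flagged) {
    cat("  comparison flagged: a stratum is empty or has rate 0\n")
  } else {
    cat(sprintf("  rate (MSR<=%d) = %.2f%%, rate (MSR>%d) = %.2f%%, increase = %.1f%% (~%d%%)\n",
                x$threshold, x$rate_low_pct, x$threshold, x$rate_high_pct,
                x$pct_increase, x$pct_increase_rounded))
  }
  invisible(x)
}

#' @rdname msr_stratify
#' @param x An `msr_strata` object.
#' @param ... Unused.
#' @method tidy msr_strata
#' @export
tidy.msr_strata <- function(x, ...) x$membership

#' @rdname msr_stratify
#' @method glance msr_strata
#' @export
glance.msr_strata <- function(x, ...) {
  tibble(
    threshold = x$threshold, rates = x$rates,
    rate_low_pct = x$rate_low_pct, rate_high_pct = x$rate_high_pct,
    pct_increase = x$pct_increase,
    pct_increase_rounded = x$pct_increase_rounded,
    flagged = x$flagged
  )
}
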