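#' Build real and sham condition-symptom survey pairs
#'
#' Samples `n_real` distinct (condition, symptom) pairs that are true
#' associations in the lexicon, and `n_sham` distinct pairs formed by
#' matching a condition with a symptom and verifying that the symptom is not
#' manifested in that condition (neither by canonical name nor by any shared
#' surface phrase). Sham pairs are the survey's negative controls.
#'
#' @param lex A `lexicon`.
#' @param n_real,n_sham Numbers of real and sham pairs (defaults 104 / 156,
#'   i.e. 260 pairs in total).
#' @param seed Optional integer seed for reproducible sampling.
#' @return Tibble `pair_id`, `condition`, `symptom`, `is_real`.
#' @export
build_pairs <- function(lex, n_real = 104, n_sham = 156, seed = NULL) {
  stopifnot(inherits(lex, "lexicon"), n_real >= 0, n_sham >= 0)
  real_all <- select(lex$symptoms, "condition", "symptom")
  if (n_real > nrow(real_all)) {
    abort(paste0("Only ", nrow(real_all), " distinct real pairs available, ",
                 n_real, " requested."))
  }
  # Candidate shams: every condition x symptom-name combination that is not
  # a real association and shares no surface phrase with the condition's own
  # symptom terms.
  spt <- symptom_phrase_table(lex)
  sham_all <- tidyr::expand_grid(
    condition = lex$conditions$condition,
    symptom = unique(lex$symptoms$symptom)
  ) %>%
    anti_join(real_all, by = c("condition", "symptom"))
  phrase_clash <- sham_all %>%
    inner_join(rename(distinct(spt[, c("symptom", "phrase")]),
                      sham_phrase = "phrase"),
               by = "symptom", relationship = "many-to-many") %>%
    inner_join(rename(spt, own_symptom = "symptom"),
               by = c("condition", "sham_phrase" = "phrase")) %>%
    distinct(.data$condition, .data$symptom)
  sham_all <- anti_join(sham_all, phrase_clash, by = c("condition", "symptom"))
  if (n_sham > nrow(sham_all)) {
    abort(paste0("Only ", nrow(sham_all), " distinct sham pairs available, ",
                 n_sham, " requested."))
  }
  draw <- function() {
    real <- real_all[sample.int(nrow(real_all), n_real), ]
    sham <- sham_all[sample.int(nrow(sham_all), n_sham), ]
    bind_rows(
      mutate(real, is_real = TRUE),
      mutate(sham, is_real = FALSE)
    ) %>%
      mutate(pair_id = dplyr::row_number()) %>%
      select("pair_id", "condition", "symptom", "is_real")
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate crowdsourced survey responses
#'
#' A synthetic stand-in for a crowdsourced recognition survey: every rater
#' answers every pair. Recognition of the condition name is Bernoulli with a
#' per-condition (or scalar) probability; the association judgement is
#' Bernoulli with probability `sensitivity` for real pairs and
#' `1 - specificity` for sham pairs.
#'
#' @param pairs Output of [build_pairs()].
#' @param n_raters Number of raters (default 10).
#' @param recognition Scalar probability, or named vector keyed by condition.
#' @param sensitivity P(associated = yes | real pair).
#' @param specificity P(associated = no | sham pair).
#' @param seed Optional integer seed.
#' @return Tibble `pair_id`, `condition`, `symptom`, `is_real`, `rater_id`,
#'   `recognized_condition`, `associated`.
#' @export
simulate_responses <- function(pairs, n_raters = 10, recognition = 0.86,
                               sensitivity = 0.86, specificity = 0.74,
                               seed = NULL) {
  stopifnot(n_raters >= 1)
  probs <- c(recognition, sensitivity, specificity)
  if (any(probs < 0 | probs > 1)) abort("Probabilities must lie in [0, 1].")
  if (is.null(names(recognition))) {
    rec <- rep(recognition[[1]], nrow(pairs))
  } else {
    miss <- setdiff(unique(pairs$condition), names(recognition))
    if (length(miss) > 0) {
      abort(paste0("`recognition` lacks condition(s): ",
                   paste(miss, collapse = ", ")))
    }
    rec <- unname(recognition[pairs$condition])
  }
  draw <- function() {
    long <- tidyr::expand_grid(rater_id = seq_len(n_raters),
                               idx = seq_len(nrow(pairs)))
    p_rec <- rec[long$idx]
    p_assoc <- ifelse(pairs$is_real[long$idx], sensitivity, 1 - specificity)
    tibble(
      pair_id = pairs$pair_id[long$idx],
      condition = pairs$condition[long$idx],
      symptom = pairs$symptom[long$idx],
      is_real = pairs$is_real[long$idx],
      rater_id = long$rater_id,
      recognized_condition = runif(nrow(long)) < p_rec,
      associated = runif(nrow(long)) < p_assoc
    ) %>%
      arrange(.data$pair_id, .data$rater_id)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Aggregate survey responses
#'
#' Response-level rates: the recognition rate (fraction of all responses
#' that recognized the condition name), real-pair accuracy (fraction of
#' real-pair responses judging the pair associated) and sham-pair accuracy
#' (fraction of sham-pair responses judging it not associated), plus
#' per-condition recognition and real-pair association rates. Every response
#' falls in exactly one of the real/sham accuracy denominators.
#'
#' @param responses Output of [simulate_responses()] (or any tibble with
#'   columns `condition`, `is_real`, `recognized_condition`, `associated`).
#' @return An object of class `survey_summary`: list with `overall` (one-row
#'   tibble: `n_responses`, `recognition_pct`, `real_accuracy_pct`,
#'   `sham_accuracy_pct`) and `by_condition` (tibble with per-condition
#'   rates). [glance()] returns `overall`, [tidy()] returns `by_condition`.
#' @export
aggregate_survey <- function(responses) {
  if (nrow(responses) == 0) abort("`responses` is empty.")
  pct_or_na <- function(x) if (length(x) == 0) NA_real_ else 100 * mean(x)
  overall <- tibble(
    n_responses = nrow(responses),
    recognition_pct = 100 * mean(responses$recognized_condition),
    real_accuracy_pct = pct_or_na(responses$associated[responses$is_real]),
    sham_accuracy_pct = pct_or_na(!responses$associated[!responses$is_real])
  )
  by_condition <- responses %>%
    group_by(.data$condition) %>%
    summarise(
      n_responses = n(),
      recognition_pct = 100 * mean(.data$recognized_condition),
      real_association_pct = pct_or_na(.data$associated[.data$is_real]),
      .groups = "drop"
    )
  structure(list(overall = overall, by_condition = by_condition),
            class = "survey_summary")
}

#' @export
print.survey_summary <- function(x, ...) {
  o <- x$overall
  cat(sprintf(
    "Survey: %d responses | recognition %.1f%% | real-pair accuracy %.1f%% | sham-pair accuracy %.1f%%\n",
    o$n_responses, o$recognition_pct, o$real_accuracy_pct, o$sham_accuracy_pct
  ))
  invisible(x)
}

#' @rdname aggregate_survey
#' @param x A `survey_summary` object.
#' @param ... Unused.
#' @method tidy survey_summary
#' @export
tidy.survey_summary <- function(x, ...) x$by_condition

#' @rdname aggregate_survey
#' @method glance survey_summary
#' @export
glance.survey_summary <- function(x, ...) x$overall

#' Correlation between symptom recognition and pre-diagnosis query rate
#'
#' Spearman correlation between per-condition recognition (how well
#' laypeople associate a condition with its symptoms) and the pre-diagnosis
#' symptom-query rate. A negative coefficient supports the hypothesis that
#' people query more for symptoms they do not recognize.
#'
#' @param recognition_pct,pct_before Equal-length numeric vectors, one entry
#'   per condition.
#' @param ... Passed to [spearman_cor()].
#' @return A `spearman_cor` object.
#' @export
knowledge_rate_correlation <- function(recognition_pct, pct_before, ...) {
  spearman_cor(recognition_pct, pct_before, ...)
}
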