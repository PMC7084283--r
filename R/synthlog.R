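#' Configure the synthetic query-log generator
#'
#' Full generative parameterization of a synthetic search log with the
#' statistical structure the analysis assumes: per-condition cohorts of
#' DAQ-issuing users, pre-diagnosis symptom queries with a configurable
#' probability and lead-time (lag) distribution, per-symptom geometric query
#' repetition, hospital queries clustered around diagnosis time (normal
#' jitter plus an optional same-day point mass), distractor users who issue
#' only excluded phrasings, and neutral background noise queries.
#'
#' @param conditions Tibble with one row per condition and columns
#'   `condition`, `cohort_size` (>= 1), `p_pre` (probability of >= 1
#'   pre-diagnosis symptom query), `lag_median_days` (median of the
#'   log-normal symptom-to-DAQ lead time, days), `lag_sdlog` (log-scale SD),
#'   `repeat_p` (geometric parameter; a queried symptom is asked about
#'   `1/repeat_p` times in expectation), `p_hospital`,
#'   `hospital_jitter_sd_days` (normal SD of the hospital-query offset from
#'   diagnosis time), `p_hospital_same_day` (point mass of hospital queries
#'   on the diagnosis date; 0 gives the pure normal-jitter model).
#' @param window_start,window_end Observation window (dates, `start < end`).
#' @param background_noise_rate Expected neutral distractor queries per user
#'   (Poisson).
#' @param p_excluded_phrasing Distractor users who issue only excluded
#'   phrasings, as a fraction of each cohort.
#' @param seed Integer seed; generation is fully deterministic under it.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(conditions,
                         window_start = "2017-05-01",
                         window_end = "2018-04-30",
                         background_noise_rate = 2,
                         p_excluded_phrasing = 0.1,
                         seed = 1L) {
  need <- c("condition", "cohort_size", "p_pre", "lag_median_days",
            "lag_sdlog", "repeat_p", "p_hospital", "hospital_jitter_sd_days",
            "p_hospital_same_day")
  miss <- setdiff(need, names(conditions))
  if (length(miss) > 0) {
    abort(paste0("`conditions` is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  probs <- c(conditions$p_pre, conditions$p_hospital,
             conditions$p_hospital_same_day, p_excluded_phrasing)
  if (any(probs < 0 | probs > 1)) abort("All probabilities must lie in [0, 1].")
  if (any(conditions$cohort_size < 1)) abort("`cohort_size` must be >= 1.")
  if (any(conditions$repeat_p <= 0 | conditions$repeat_p > 1)) {
    abort("`repeat_p` must lie in (0, 1].")
  }
  ws <- as.POSIXct(paste0(window_start, " 00:00:00"), tz = "UTC")
  we <- as.POSIXct(paste0(window_end, " 23:59:59"), tz = "UTC")
  if (!(ws < we)) abort("`window_start` must precede `window_end`.")
  structure(
    list(conditions = as_tibble(conditions), window_start = ws,
         window_end = we, background_noise_rate = background_noise_rate,
         p_excluded_phrasing = p_excluded_phrasing, seed = as.integer(seed)),
    class = "synth_config"
  )
}

# Neutral background phrases; screened at generation time so that no
# lexicon phrase occurs in any of them (keeps ground truth exact).
noise_pool <- function(lex) {
  pool <- c(
    "weather forecast tomorrow", "cheap flights to denver",
    "pizza delivery near me", "football scores tonight",
    "how to fix a leaky faucet", "best laptop deals this week",
    "movie showtimes downtown", "chocolate chip cookie recipe",
    "used cars for sale", "tax filing deadline", "local news today",
    "baseball standings", "knitting patterns for beginners",
    "garden fence ideas", "phone battery replacement guide",
    "bus schedule downtown", "crossword puzzle answers",
    "currency exchange rates", "guitar chords for beginners",
    "library opening times"
  )
  padded <- pad_text(normalize_text(pool))
  clash <- rep(FALSE, length(pool))
  for (ph in all_lexicon_phrases(lex)) {
    clash <- clash | grepl(paste0(" ", ph, " "), padded, fixed = TRUE)
  }
  pool[!clash]
}

daq_templates <- c("i have %s", "i was diagnosed with %s",
                   "i have been diagnosed with %s", "just diagnosed with %s")
distractor_templates <- c("do i have %s", "i think i have %s",
                          "my husband was diagnosed with %s",
                          "my wife has %s i have questions")
hospital_templates <- c("%s near me", "directions to the %s",
                        "%s visiting hours")

#' Generate a synthetic query log with ground truth
#'
#' Draws, for every condition in the configuration, a cohort of users with a
#' diagnosis time uniform in the observation window; each user issues one
#' DAQ (rendered from "i have ..." / "diagnosed with ..." templates on a
#' random condition alias) at a random second of the diagnosis day. With
#' probability `p_pre` the user picks one symptom term of the condition and
#' queries a random surface phrase of it `1 + Geometric(repeat_p)` times,
#' the first query a log-normal lead time before the DAQ (always at least
#' one second earlier, so the strict "before" rule is exercised
#' deterministically) and repeats between then and the DAQ. With probability
#' `p_hospital` a hospital query is placed at the diagnosis time plus normal
#' jitter, or on the diagnosis date itself with probability
#' `p_hospital_same_day`. Distractor users issue only excluded phrasings;
#' all users emit Poisson background noise from a neutral phrase pool that
#' is screened against the lexicon, so noise never creates symptom or DAQ
#' matches.
#'
#' @param cfg A [synth_config()].
#' @param lex A `lexicon`; every configured condition must exist in it.
#' @return List with `log` (tibble `user_id`, `timestamp`, `text`, sorted by
#'   user then time) and `truth` (tibble `user_id`, `condition`, `category`
#'   = case/distractor, `t_diagnosis`, `pre_diagnosis`, `symptom`,
#'   `n_symptom_queries`, `has_hospital`). Identical seeds give identical
#'   output.
#' @export
generate_log <- function(cfg, lex) {
  stopifnot(inherits(cfg, "synth_config"), inherits(lex, "lexicon"))
  unknown <- setdiff(cfg$conditions$condition, lex$conditions$condition)
  if (length(unknown) > 0) {
    abort(paste0("Configured condition(s) not in lexicon: ",
                 paste(unknown, collapse = ", ")))
  }
  withr::with_seed(cfg$seed, generate_log_impl(cfg, lex))
}

generate_log_impl <- function(cfg, lex) {
  t0 <- as.numeric(cfg$window_start)
  t1 <- as.numeric(cfg$window_end)
  at <- alias_table(lex)
  pool <- noise_pool(lex)
  logs <- list()
  truths <- list()

  for (ci in seq_len(nrow(cfg$conditions))) {
    cc <- cfg$conditions[ci, ]
    cname <- cc$condition
    n <- cc$cohort_size
    ids <- sprintf("c%02d_u%05d", ci, seq_len(n))
    aliases <- at$alias[at$condition == cname]
    sy <- filter(lex$symptoms, .data$condition == cname)

    t_daq <- floor(t0 + runif(n) * (t1 - t0))
    daq_text <- sprintf(sample(daq_templates, n, replace = TRUE),
                        aliases[sample.int(length(aliases), n, replace = TRUE)])

    pre <- runif(n) < cc$p_pre
    np <- sum(pre)
    sym_name <- rep(NA_character_, n)
    n_sym_q <- rep(0L, n)
    sym_log <- NULL
    if (np > 0) {
      srow <- sample.int(nrow(sy), np, replace = TRUE)
      sym_name[pre] <- sy$symptom[srow]
      phrase <- vapply(srow, function(j) {
        p <- sy$phrases[[j]]
        p[[sample.int(length(p), 1L)]]
      }, character(1))
      lag_secs <- pmax(rlnorm(np, meanlog = log(cc$lag_median_days),
                              sdlog = cc$lag_sdlog) * 86400, 1)
      t_first <- floor(t_daq[pre] - lag_secs)
      k <- 1L + rgeom(np, cc$repeat_p)
      n_sym_q[pre] <- k
      extra <- k - 1L
      rep_idx <- rep(seq_len(np), times = extra)
      t_extra <- floor(t_first[rep_idx] +
                         runif(length(rep_idx)) *
                           (t_daq[pre][rep_idx] - 1 - t_first[rep_idx]))
      sym_log <- tibble(
        user_id = c(ids[pre], ids[pre][rep_idx]),
        ts = c(t_first, t_extra),
        text = c(phrase, phrase[rep_idx])
      )
    }

    hosp <- runif(n) < cc$p_hospital
    nh <- sum(hosp)
    hosp_log <- NULL
    if (nh > 0) {
      same <- runif(nh) < cc$p_hospital_same_day
      t_h <- numeric(nh)
      day_start <- (t_daq[hosp] %/% 86400) * 86400
      t_h[same] <- day_start[same] + floor(runif(sum(same)) * 86400)
      t_h[!same] <- floor(t_daq[hosp][!same] +
                            rnorm(sum(!same), 0, cc$hospital_jitter_sd_days) * 86400)
      terms <- lex$hospital_terms[sample.int(length(lex$hospital_terms), nh,
                                             replace = TRUE)]
      hosp_log <- tibble(
        user_id = ids[hosp], ts = t_h,
        text = sprintf(sample(hospital_templates, nh, replace = TRUE), terms)
      )
    }

    m <- round(cfg$p_excluded_phrasing * n)
    dist_log <- NULL
    dist_ids <- character(0)
    if (m > 0) {
      dist_ids <- sprintf("x%02d_u%05d", ci, seq_len(m))
      dist_log <- tibble(
        user_id = dist_ids,
        ts = floor(t0 + runif(m) * (t1 - t0)),
        text = sprintf(sample(distractor_templates, m, replace = TRUE),
                       aliases[sample.int(length(aliases), m, replace = TRUE)])
      )
    }

    all_ids <- c(ids, dist_ids)
    n_noise <- rpois(length(all_ids), cfg$background_noise_rate)
    noise_log <- NULL
    if (sum(n_noise) > 0 && length(pool) > 0) {
      who <- rep(all_ids, times = n_noise)
      noise_log <- tibble(
        user_id = who,
        ts = floor(t0 + runif(length(who)) * (t1 - t0)),
        text = pool[sample.int(length(pool), length(who), replace = TRUE)]
      )
    }

    logs[[ci]] <- bind_rows(
      tibble(user_id = ids, ts = t_daq, text = daq_text),
      sym_log, hosp_log, dist_log, noise_log
    )
    truths[[ci]] <- bind_rows(
      tibble(
        user_id = ids, condition = cname, category = "case",
        t_diagnosis = t_daq, pre_diagnosis = pre, symptom = sym_name,
        n_symptom_queries = n_sym_q, has_hospital = hosp
      ),
      if (m > 0) tibble(
        user_id = dist_ids, condition = cname, category = "distractor",
        t_diagnosis = NA_real_, pre_diagnosis = FALSE,
        symptom = NA_character_, n_symptom_queries = 0L, has_hospital = FALSE
      )
    )
  }

  log <- bind_rows(logs) %>%
    mutate(timestamp = as.POSIXct(.data$ts, origin = "1970-01-01", tz = "UTC")) %>%
    select("user_id", "timestamp", "text") %>%
    arrange(.data$user_id, .data$timestamp, .data$text)
  truth <- bind_rows(truths) %>%
    mutate(t_diagnosis = as.POSIXct(.data$t_diagnosis, origin = "1970-01-01",
                                    tz = "UTC")) %>%
    arrange(.data$condition, .data$user_id)
  list(log = log, truth = truth)
}

#' Ready-made generator scenario mirroring the reference study conditions
#'
#' Builds a [synth_config()] for the 20 bundled reference conditions whose
#' cohort sizes are the observed cohort sizes scaled by `scale` and whose
#' pre-diagnosis probabilities are the observed per-condition percentages
#' divided by 100. The median symptom-to-DAQ lead time is set to
#' `100 * p_pre` days, so lead time increases with the pre-diagnosis rate
#' and the positive lag-rate association is built into the scenario by
#' construction.
#'
#' Remaining defaults are held at the study conditions: geometric repeat
#' parameter `1/1.7` (1.7 queries per queried symptom in expectation),
#' hospital-query probability 0.6, hospital jitter SD 17 days with a 0.19
#' same-day mass, background noise 2 queries/user, 10% distractor users.
#'
#' @param scale Cohort scale factor in (0, 1].
#' @param seed Integer seed for [synth_config()].
#' @return A `synth_config` for use with [generate_log()] and
#'   [default_lexicon()].
#' @export
scenario_reference <- function(scale = 1, seed = 1L) {
  stopifnot(scale > 0, scale <= 1)
  ref <- reference_condition_counts()
  synth_config(
    conditions = tibble(
      condition = ref$condition,
      cohort_size = pmax(1L, as.integer(round(ref$n_total * scale))),
      p_pre = ref$pct_before / 100,
      lag_median_days = pmax(1, 100 * ref$pct_before / 100),
      lag_sdlog = 0.5,
      repeat_p = 1 / 1.7,
      p_hospital = 0.6,
      hospital_jitter_sd_days = 17,
      p_hospital_same_day = 0.19
    ),
    seed = seed
  )
}
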