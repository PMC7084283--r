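#' Classify a single query as a diagnosis ascertainment query (DAQ)
#'
#' A query is a DAQ for condition *c* when it matches at least one DAQ
#' inclusion phrase ("i have" / "diagnosed with" by default), matches at
#' least one alias of *c*, and matches none of the exclusion phrases
#' (hypothetical phrasings such as "do i have" and third-party words such as
#' "wife" or "dog"). The inclusion phrase and the alias may occur anywhere in
#' the query, in any order. A query matching aliases of several conditions is
#' a DAQ for each of them.
#'
#' @param text A single query string (raw; normalized internally).
#' @param lex A `lexicon`.
#' @return Character vector of condition names (possibly empty).
#' @examples
#' lex <- default_lexicon()
#' classify_daq("I was diagnosed with COPD", lex)
#' classify_daq("do I have COPD", lex)  # excluded phrasing -> character(0)
#' @export
classify_daq <- function(text, lex) {
  stopifnot(length(text) == 1L, inherits(lex, "lexicon"))
  hits <- daq_hits(tibble(user_id = "u", timestamp = Sys.time(), text = text), lex)
  hits$condition
}

#' Attribute symptom mentions in a single query
#'
#' Returns every (condition, symptom) pair for which any surface phrase of
#' that symptom term occurs in the query, in deterministic (condition,
#' symptom) order. A symptom phrase shared by several conditions yields one
#' row per condition.
#'
#' @inheritParams classify_daq
#' @return Tibble with columns `condition`, `symptom` (zero rows when
#'   nothing matches).
#' @export
classify_symptoms <- function(text, lex) {
  stopifnot(length(text) == 1L, inherits(lex, "lexicon"))
  hits <- symptom_hits(tibble(user_id = "u", timestamp = Sys.time(), text = text), lex)
  select(hits, "condition", "symptom")
}

#' Is a query a hospital/clinic query?
#'
#' True when any hospital term ("hospital", "medical center", "clinic", ...)
#' occurs as a whole-token phrase; "hospitality" does not match.
#'
#' @param text Character vector of query strings.
#' @param lex A `lexicon`.
#' @return Logical vector.
#' @export
classify_hospital <- function(text, lex) {
  stopifnot(inherits(lex, "lexicon"))
  match_any_padded(pad_text(normalize_text(text)), lex$hospital_terms)
}

# ---- vectorized long-format matchers (the pipeline's workhorses) ----------

check_log_frame <- function(log) {
  need <- c("user_id", "timestamp", "text")
  miss <- setdiff(need, names(log))
  if (length(miss) > 0) {
    abort(paste0("Query log is missing column(s): ", paste(miss, collapse = ", ")))
  }
  invisible(log)
}

# tibble(user_id, timestamp, condition): one row per DAQ hit.
daq_hits <- function(log, lex) {
  check_log_frame(log)
  padded <- pad_text(normalize_text(log$text))
  incl <- match_any_padded(padded, lex$daq_include)
  excl <- match_any_padded(padded, lex$daq_exclude)
  eligible <- incl & !excl
  out <- list()
  at <- alias_table(lex)
  for (cname in lex$conditions$condition) {
    aliases <- at$alias[at$condition == cname]
    idx <- which(eligible & match_any_padded(padded, aliases))
    if (length(idx) > 0) {
      out[[cname]] <- tibble(
        user_id = log$user_id[idx],
        timestamp = log$timestamp[idx],
        condition = cname
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(user_id = character(), timestamp = log$timestamp[0],
                  condition = character()))
  }
  arrange(bind_rows(out), .data$condition, .data$user_id, .data$timestamp)
}

# tibble(user_id, timestamp, condition, symptom): one row per matched term.
symptom_hits <- function(log, lex) {
  check_log_frame(log)
  padded <- pad_text(normalize_text(log$text))
  spt <- symptom_phrase_table(lex)
  out <- vector("list", length(unique(spt$phrase)))
  k <- 0L
  for (ph in unique(spt$phrase)) {
    idx <- which(grepl(paste0(" ", ph, " "), padded, fixed = TRUE))
    if (length(idx) == 0) next
    owners <- spt[spt$phrase == ph, c("condition", "symptom")]
    k <- k + 1L
    out[[k]] <- tibble(
      row = rep(idx, times = nrow(owners)),
      condition = rep(owners$condition, each = length(idx)),
      symptom = rep(owners$symptom, each = length(idx))
    )
  }
  if (k == 0L) {
    return(tibble(user_id = character(), timestamp = log$timestamp[0],
                  condition = character(), symptom = character()))
  }
  hits <- distinct(bind_rows(out[seq_len(k)]))
  tibble(
    user_id = log$user_id[hits$row],
    timestamp = log$timestamp[hits$row],
    condition = hits$condition,
    symptom = hits$symptom
  ) %>%
    arrange(.data$condition, .data$symptom, .data$user_id, .data$timestamp)
}

# tibble(user_id, timestamp): one row per hospital query.
hospital_hits <- function(log, lex) {
  check_log_frame(log)
  idx <- which(classify_hospital(log$text, lex))
  tibble(user_id = log$user_id[idx], timestamp = log$timestamp[idx])
}

#' Label every query in a log
#'
#' Vectorized classification of a whole query log: DAQ status (with the
#' conditions ascertained), symptom-term hits, and hospital-query status.
#' This is the per-query export surface; [build_timelines()] consumes the
#' same matchers directly.
#'
#' @param log Tibble with columns `user_id`, `timestamp`, `text`.
#' @param lex A `lexicon`.
#' @return The input tibble plus columns `is_daq` (logical),
#'   `daq_conditions` (semicolon-joined condition names, `""` when none),
#'   `symptom_hits` (semicolon-joined `condition:symptom` pairs), and
#'   `is_hospital` (logical).
#' @export
label_queries <- function(log, lex) {
  check_log_frame(log)
  log <- as_tibble(log)
  key <- seq_len(nrow(log))
  logk <- mutate(log, .row = key)

  dh <- daq_hits(mutate(logk, user_id = as.character(.data$.row)), lex) %>%
    group_by(.data$user_id) %>%
    summarise(daq_conditions = paste(sort(unique(.data$condition)), collapse = ";"),
              .groups = "drop") %>%
    mutate(.row = as.integer(.data$user_id)) %>%
    select(".row", "daq_conditions")

  sh <- symptom_hits(mutate(logk, user_id = as.character(.data$.row)), lex) %>%
    mutate(pair = paste0(.data$condition, ":", .data$symptom)) %>%
    group_by(.data$user_id) %>%
    summarise(symptom_hits = paste(sort(unique(.data$pair)), collapse = ";"),
              .groups = "drop") %>%
    mutate(.row = as.integer(.data$user_id)) %>%
    select(".row", "symptom_hits")

  out <- logk %>%
    left_join(dh, by = ".row") %>%
    left_join(sh, by = ".row") %>%
    mutate(
      daq_conditions = dplyr::coalesce(.data$daq_conditions, ""),
      symptom_hits = dplyr::coalesce(.data$symptom_hits, ""),
      is_daq = nzchar(.data$daq_conditions),
      is_hospital = classify_hospital(log$text, lex)
    ) %>%
    select(-".row") %>%
    select("user_id", "timestamp", "text", "is_daq", "daq_conditions",
           "symptom_hits", "is_hospital")
  out
}
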