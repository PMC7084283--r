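# Small constructed lexicon with MSR values (the bundled lexicon ships
# without ranks), used wherever severity logic or hand-enumerable matching
# is needed.
toy_lexicon <- function() {
  as_lexicon(list(
    list(
      name = "alpha fever",
      aliases = list("alpha fever", "af"),
      symptoms = list(
        list(name = "headache", phrases = list("headache", "head pain"), msr = 3),
        list(name = "rash", phrases = list("rash"), msr = 2)
      )
    ),
    list(
      name = "beta pox",
      aliases = list("beta pox"),
      symptoms = list(
        list(name = "cough", phrases = list("cough"), msr = 5),
        list(name = "fever spots", phrases = list("fever spots"), msr = 8)
      )
    ),
    list(
      name = "gamma flu",
      aliases = list("gamma flu"),
      symptoms = list(
        list(name = "chills", phrases = list("chills"))
      )
    )
  ))
}

t_base <- as.POSIXct("2017-06-01 12:00:00", tz = "UTC")

# Query log from (user, day-offset, text) triples.
make_log <- function(...) {
  rows <- list(...)
  tibble::tibble(
    user_id = vapply(rows, function(r) as.character(r[[1]]), character(1)),
    timestamp = t_base +
      vapply(rows, function(r) as.numeric(r[[2]]), numeric(1)) * 86400,
    text = vapply(rows, function(r) as.character(r[[3]]), character(1))
  )
}

# Timelines with given signed hospital lags (days) relative to a fixed DAQ.
make_hospital_timelines <- function(lags_days, condition = "alpha fever") {
  n <- length(lags_days)
  tibble::tibble(
    user_id = sprintf("u%03d", seq_len(n)),
    condition = condition,
    t_first_daq = t_base,
    t_first_symptom = as.POSIXct(NA, tz = "UTC"),
    symptom_before_daq = FALSE,
    symptom_query_count = 0L,
    symptom_counts = vector("list", n),
    t_first_hospital = t_base + ifelse(is.na(lags_days), NA, lags_days) * 86400
  )
}

# Independent naive phrase matcher: explicit token split and sliding-window
# comparison, no shared code with the package matcher.
naive_match <- function(text, phrase) {
  norm <- function(s) {
    s <- tolower(s)
    s <- gsub("[^a-z0-9']+", " ", s)
    strsplit(trimws(s), " +")[[1]]
  }
  tt <- norm(text)
  pp <- norm(phrase)
  if (length(pp) == 0 || length(tt) < length(pp)) return(FALSE)
  for (i in seq_len(length(tt) - length(pp) + 1)) {
    if (all(tt[i:(i + length(pp) - 1)] == pp)) return(TRUE)
  }
  FALSE
}

# Naive DAQ rule re-verification built on the naive matcher.
naive_daq <- function(text, lex) {
  any_m <- function(phrases) any(vapply(phrases, naive_match, logical(1), text = text))
  if (!any_m(lex$daq_include) || any_m(lex$daq_exclude)) return(character(0))
  at <- prediag:::alias_table(lex)
  hits <- vapply(split(at$alias, at$condition), any_m, logical(1))
  sort(names(hits)[hits])
}
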