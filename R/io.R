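#' Read and write query logs
#'
#' Query logs are tab-separated UTF-8 text with a header row and columns
#' `user_id`, `timestamp` (ISO-8601, second resolution, timezone-naive;
#' interpreted as UTC), and `text`. In strict mode (the default) any
#' unparseable timestamp or empty field aborts the read with the offending
#' line numbers; in lenient mode such records are dropped with a warning.
#' Silent data loss is worse than an explicit rerun, hence strict is the
#' default.
#'
#' @param path File path.
#' @param strict Abort on bad records (`TRUE`, default) or drop them with a
#'   warning (`FALSE`).
#' @return Tibble `user_id`, `timestamp` (POSIXct, UTC), `text`.
#' @export
read_query_log <- function(path, strict = TRUE) {
  raw <- readr::read_tsv(path, col_types = "ccc", progress = FALSE)
  check_log_frame(raw)
  ts <- as.POSIXct(sub("T", " ", raw$timestamp, fixed = TRUE),
                   tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  bad <- is.na(ts) | is.na(raw$user_id) | !nzchar(raw$user_id) |
    is.na(raw$text) | !nzchar(normalize_text(dplyr::coalesce(raw$text, "")))
  if (any(bad)) {
    lines <- which(bad) + 1L  # + header line
    msg <- paste0(sum(bad), " bad record(s) at file line(s) ",
                  paste(head(lines, 10), collapse = ", "),
                  if (sum(bad) > 10) ", ..." else "")
    if (strict) abort(paste0(msg, " (strict mode; use strict = FALSE to drop)"))
    warn(paste0(msg, "; dropped (lenient mode)"))
  }
  tibble(user_id = raw$user_id[!bad], timestamp = ts[!bad],
         text = raw$text[!bad])
}

#' @rdname read_query_log
#' @param log Tibble `user_id`, `timestamp` (POSIXct), `text`.
#' @export
write_query_log <- function(log, path) {
  check_log_frame(log)
  out <- mutate(as_tibble(log),
                timestamp = format(.data$timestamp, "%Y-%m-%dT%H:%M:%S",
                                   tz = "UTC"))
  readr::write_tsv(out[, c("user_id", "timestamp", "text")], path,
                   progress = FALSE)
  invisible(path)
}

# Flatten timelines for TSV export (list-column dropped; ISO timestamps).
flatten_timelines <- function(timelines) {
  timelines %>%
    select(-"symptom_counts") %>%
    mutate(across(
      c("t_first_daq", "t_first_symptom", "t_first_hospital"),
      ~ format(.x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    ))
}
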