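#' Normalize query or lexicon text
#'
#' Lowercases, strips every character outside letters, digits and the
#' apostrophe, and collapses runs of whitespace to single spaces. All phrase
#' matching in the package operates on this normalized form, so matching is
#' insensitive to case and punctuation but respects token boundaries
#' ("haven't" is a single token and never matches the phrase "have").
#'
#' Normalization is idempotent: applying it to already-normalized text is the
#' identity.
#'
#' @param x Character vector.
#' @return Character vector of the same length, normalized.
#' @examples
#' normalize_text("I was Diagnosed With COPD!")
#' @export
normalize_text <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9']+", " ", x)
  trimws(x)
}

#' Match a phrase as a contiguous token subsequence
#'
#' Returns `TRUE` where `phrase` occurs as a contiguous run of whole tokens
#' inside `text`. Both sides are normalized with [normalize_text()] unless
#' `normalize = FALSE`. Token-level matching prevents substring false hits:
#' the phrase "hospital" does not match "hospitality", and "i have" does not
#' match "i haven't".
#'
#' @param text Character vector of query texts.
#' @param phrase A single phrase (character scalar).
#' @param normalize Normalize both sides first? Default `TRUE`.
#' @return Logical vector, one element per entry of `text`.
#' @examples
#' match_phrase("do i have copd", "i have")     # TRUE: contiguous tokens
#' match_phrase("i haven't slept", "i have")    # FALSE: token boundary
#' match_phrase("hospitality jobs", "hospital") # FALSE
#' @export
match_phrase <- function(text, phrase, normalize = TRUE) {
  stopifnot(length(phrase) == 1L)
  if (normalize) {
    text <- normalize_text(text)
    phrase <- normalize_text(phrase)
  }
  if (!nzchar(phrase)) {
    abort("`phrase` is empty after normalization.")
  }
  grepl(paste0(" ", phrase, " "), paste0(" ", text, " "), fixed = TRUE)
}

# Any-of matcher over a set of phrases; `padded` must already be normalized
# and wrapped in single leading/trailing spaces.
match_any_padded <- function(padded, phrases) {
  out <- rep(FALSE, length(padded))
  for (p in phrases) {
    out <- out | grepl(paste0(" ", p, " "), padded, fixed = TRUE)
  }
  out
}

pad_text <- function(normalized) paste0(" ", normalized, " ")
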