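#' Default diagnosis-ascertainment phrase lists
#'
#' The inclusion phrases that mark a query as a candidate diagnosis
#' ascertainment query (DAQ), and the exclusion phrases that veto it
#' (hypothetical phrasings and third-party references). These are the rule
#' defaults used whenever a lexicon file does not override them.
#'
#' @return Character vector of normalized phrases.
#' @export
daq_include_default <- function() c("i have", "diagnosed with")

#' @rdname daq_include_default
#' @export
daq_exclude_default <- function() {
  c("do i have", "can i have", "i think i have", "did i have",
    "nurse", "patient", "cat", "dog", "wife", "husband", "son", "daughter")
}

#' @rdname daq_include_default
#' @export
hospital_terms_default <- function() {
  c("hospital", "hospitals", "medical center", "clinic")
}

#' Construct a lexicon
#'
#' A lexicon parameterizes every matcher in the pipeline: the medical
#' conditions and their surface aliases, each condition's symptom terms
#' (canonical label, surface phrases, optional Medical Severity Rank), the
#' DAQ inclusion/exclusion phrases, and the hospital/clinic terms. MSR is a
#' 1-10 perceived-urgency rank (1 = requires immediate urgent care, 10 = can
#' be disregarded).
#'
#' All phrases are normalized (see [normalize_text()]) and the lexicon is
#' canonicalised: conditions, symptoms and phrases are sorted, so two
#' lexicons with the same content compare equal regardless of input order.
#'
#' @param conditions A list of condition entries; each entry is a list with
#'   elements `name` (scalar), `aliases` (character), and `symptoms` (a list
#'   of lists with `name`, `phrases`, and optional `msr`).
#' @param daq_include,daq_exclude,hospital_terms Character phrase vectors;
#'   `NULL` means the package defaults.
#' @return An object of class `lexicon`: a list with elements
#'   * `conditions`: tibble (`condition`, `aliases` list-column),
#'   * `symptoms`: tibble (`condition`, `symptom`, `msr`, `phrases` list-column),
#'   * `daq_include`, `daq_exclude`, `hospital_terms`: character vectors.
#' @seealso [load_lexicon()], [write_lexicon()], [default_lexicon()]
#' @export
as_lexicon <- function(conditions, daq_include = NULL, daq_exclude = NULL,
                       hospital_terms = NULL) {
  if (length(conditions) == 0) abort("A lexicon needs at least one condition.")
  norm_phrases <- function(x, what) {
    x <- normalize_text(as.character(x))
    x <- unique(x[nzchar(x)])
    if (length(x) == 0) abort(paste0(what, ": no non-empty phrases."))
    sort(x)
  }

  cond_rows <- list()
  sym_rows <- list()
  for (ce in conditions) {
    if (is.null(ce$name) || !nzchar(normalize_text(ce$name))) {
      abort("A condition entry is missing its name.")
    }
    cname <- normalize_text(ce$name)
    if (is.null(ce$aliases) || length(ce$aliases) == 0) {
      abort(paste0("Condition '", cname, "': aliases must be non-empty."))
    }
    if (is.null(ce$symptoms) || length(ce$symptoms) == 0) {
      abort(paste0("Condition '", cname, "': symptom list must be non-empty."))
    }
    aliases <- norm_phrases(ce$aliases, paste0("Condition '", cname, "' aliases"))
    seen_phrases <- character(0)
    for (se in ce$symptoms) {
      if (is.null(se$name) || !nzchar(normalize_text(se$name))) {
        abort(paste0("Condition '", cname, "': a symptom is missing its name."))
      }
      sname <- normalize_text(se$name)
      phrases <- norm_phrases(
        se$phrases %||% se$name,
        paste0("Symptom '", sname, "' of '", cname, "'")
      )
      dup <- intersect(phrases, seen_phrases)
      if (length(dup) > 0) {
        abort(paste0(
          "Condition '", cname, "': phrase '", dup[[1]],
          "' is shared by two symptom terms; attribution must be unambiguous."
        ))
      }
      seen_phrases <- c(seen_phrases, phrases)
      msr <- se$msr
      if (!is.null(msr) && !is.na(msr)) {
        if (!is.numeric(msr) || length(msr) != 1 || msr != as.integer(msr) ||
            msr < 1 || msr > 10) {
          abort(paste0(
            "Symptom '", sname, "' of '", cname,
            "': msr must be an integer in 1..10 (got ", format(msr), ")."
          ))
        }
        msr <- as.integer(msr)
      } else {
        msr <- NA_integer_
      }
      sym_rows[[length(sym_rows) + 1L]] <- tibble(
        condition = cname, symptom = sname, msr = msr, phrases = list(phrases)
      )
    }
    cond_rows[[length(cond_rows) + 1L]] <- tibble(
      condition = cname, aliases = list(aliases)
    )
  }
  conditions_tbl <- bind_rows(cond_rows)
  if (anyDuplicated(conditions_tbl$condition)) {
    d <- conditions_tbl$condition[duplicated(conditions_tbl$condition)][[1]]
    abort(paste0("Duplicate condition name: '", d, "'."))
  }
  conditions_tbl <- arrange(conditions_tbl, .data$condition)
  symptoms_tbl <- arrange(bind_rows(sym_rows), .data$condition, .data$symptom)
  if (anyDuplicated(symptoms_tbl[, c("condition", "symptom")])) {
    abort("Duplicate symptom name within a condition.")
  }

  lex <- structure(
    list(
      conditions = conditions_tbl,
      symptoms = symptoms_tbl,
      daq_include = sort(unique(normalize_text(daq_include %||% daq_include_default()))),
      daq_exclude = sort(unique(normalize_text(daq_exclude %||% daq_exclude_default()))),
      hospital_terms = sort(unique(normalize_text(hospital_terms %||% hospital_terms_default())))
    ),
    class = "lexicon"
  )
  lex
}

#' @export
print.lexicon <- function(x, ...) {
  cat("<lexicon> ", nrow(x$conditions), " conditions, ",
      nrow(x$symptoms), " symptom terms, ",
      sum(!is.na(x$symptoms$msr)), " with MSR\n", sep = "")
  invisible(x)
}

#' Load a lexicon from a YAML config file
#'
#' The schema has top-level keys `conditions` (a list of `name` / `aliases` /
#' `symptoms`, each symptom a `name` / `phrases` / optional `msr`),
#' and optional `daq_include`, `daq_exclude`, `hospital_terms` phrase lists
#' (package defaults apply when omitted). All phrases are normalized on load
#' and the result is validated; schema violations raise an error naming the
#' offending entry.
#'
#' @param path Path to a YAML lexicon file.
#' @return A validated [as_lexicon()] object.
#' @export
load_lexicon <- function(path) {
  if (!file.exists(path)) abort(paste0("Lexicon file not found: ", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw$conditions)) abort("Lexicon file has no `conditions` key.")
  as_lexicon(
    conditions = raw$conditions,
    daq_include = raw$daq_include,
    daq_exclude = raw$daq_exclude,
    hospital_terms = raw$hospital_terms
  )
}

#' Write a lexicon to a YAML config file
#'
#' Emits the canonical sorted form, so writing and re-loading a lexicon
#' round-trips exactly and diffs are stable.
#'
#' @param lex A `lexicon` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lex, path) {
  stopifnot(inherits(lex, "lexicon"))
  conds <- lapply(seq_len(nrow(lex$conditions)), function(i) {
    cname <- lex$conditions$condition[[i]]
    sy <- filter(lex$symptoms, .data$condition == cname)
    list(
      name = cname,
      aliases = as.list(lex$conditions$aliases[[i]]),
      symptoms = lapply(seq_len(nrow(sy)), function(j) {
        out <- list(name = sy$symptom[[j]], phrases = as.list(sy$phrases[[j]]))
        if (!is.na(sy$msr[[j]])) out$msr <- sy$msr[[j]]
        out
      })
    )
  })
  yaml::write_yaml(
    list(
      daq_include = as.list(lex$daq_include),
      daq_exclude = as.list(lex$daq_exclude),
      hospital_terms = as.list(lex$hospital_terms),
      conditions = conds
    ),
    path
  )
  invisible(path)
}

#' The bundled default lexicon
#'
#' Twenty medical conditions with evident symptoms that are neither screened
#' systematically nor usually diagnosed in asymptomatic people, together with
#' their symptom terms and common surface synonyms, shipped as a YAML file
#' under `inst/extdata/`. MSR values are not bundled (they are user-supplied
#' inputs); severity stratification on this lexicon is therefore flagged
#' until ranks are added.
#'
#' @return A `lexicon` object with 20 conditions.
#' @export
default_lexicon <- function() {
  load_lexicon(system.file("extdata", "default_lexicon.yaml",
                           package = "prediag", mustWork = TRUE))
}

#' Minimum Medical Severity Rank per condition
#'
#' A condition's severity label is the lowest (most worrying) MSR across its
#' symptom terms; conditions with no ranked symptom get `NA` and are excluded
#' from severity stratification.
#'
#' @param lex A `lexicon` object.
#' @param condition Optional single condition name; if supplied, the scalar
#'   minimum (integer or `NA`) is returned instead of the full table.
#' @return A tibble (`condition`, `min_msr`), or a scalar when `condition`
#'   is given.
#' @export
min_msr <- function(lex, condition = NULL) {
  stopifnot(inherits(lex, "lexicon"))
  tbl <- lex$symptoms %>%
    group_by(.data$condition) %>%
    summarise(
      min_msr = if (all(is.na(.data$msr))) NA_integer_
                else min(.data$msr, na.rm = TRUE),
      .groups = "drop"
    )
  if (is.null(condition)) return(tbl)
  condition <- normalize_text(condition)
  if (!condition %in% tbl$condition) {
    abort(paste0("Unknown condition: '", condition, "'."))
  }
  tbl$min_msr[tbl$condition == condition][[1]]
}

# Long (condition, symptom, phrase) table used by the matchers.
symptom_phrase_table <- function(lex) {
  tidyr::unnest(
    select(lex$symptoms, "condition", "symptom", "phrases"),
    cols = "phrases"
  ) %>%
    rename(phrase = "phrases")
}

# Long (condition, alias) table.
alias_table <- function(lex) {
  tidyr::unnest(lex$conditions, cols = "aliases") %>%
    rename(alias = "aliases")
}

# Every phrase known to the lexicon, used to screen the synthetic noise pool.
all_lexicon_phrases <- function(lex) {
  unique(c(
    alias_table(lex)$alias,
    symptom_phrase_table(lex)$phrase,
    lex$daq_include, lex$daq_exclude, lex$hospital_terms
  ))
}
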