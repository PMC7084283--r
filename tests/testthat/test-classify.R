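lex <- default_lexicon()

test_that("the DAQ rule handles the canonical worked examples", {
  expect_equal(classify_daq("I was diagnosed with COPD", lex),
               "chronic obstructive pulmonary disorder")
  expect_equal(classify_daq("i have copd", lex),
               "chronic obstructive pulmonary disorder")
  expect_length(classify_daq("do I have COPD", lex), 0)
  expect_length(classify_daq("i have a dog with lymphoma", lex), 0)
  expect_length(classify_daq("copd treatment options", lex), 0)  # no include
  expect_length(classify_daq("i have a headache", lex), 0)       # no alias
  # include phrase and alias may sit anywhere, in any order
  expect_equal(classify_daq("recently diagnosed with a bad case of gout", lex),
               "gout")
  # multiple conditions ascertained at once
  expect_setequal(classify_daq("i have gout and lymphoma", lex),
                  c("gout", "lymphoma"))
})

test_that("symptom attribution finds all owning conditions, in order", {
  hit <- classify_symptoms("chest pain when walking", lex)
  # "chest pain" belongs to the coronary condition; the bare token "pain" is
  # additionally a gout symptom term, so the same query hits gout too
  expect_equal(hit$condition,
               c("angina pectoris or coronary heart disease", "gout"))
  expect_equal(hit$symptom, c("chest pain", "pain"))
  wl <- classify_symptoms("weight loss", lex)
  expect_equal(wl$condition, sort(c("crohn disease", "graves disease",
                                    "esophageal cancer", "lymphoma")))
  expect_true(all(wl$symptom == "weight loss"))
  expect_equal(nrow(classify_symptoms("pizza near me", lex)), 0)
})

test_that("hospital classification is token-bounded", {
  expect_true(classify_hospital("memorial hospital visiting hours", lex))
  expect_true(classify_hospital("oncology clinic near me", lex))
  expect_true(classify_hospital("nearest medical center", lex))
  expect_false(classify_hospital("hospitality jobs", lex))
  expect_false(classify_hospital("clinical trial results", lex))
})

test_that("every detected DAQ re-verifies under an independent naive scanner", {
  cfg <- scenario_reference(scale = 0.01, seed = 31)
  gl <- generate_log(cfg, default_lexicon())
  labeled <- label_queries(gl$log, lex)
  set.seed(31)
  idx <- sample(nrow(labeled), 400)
  for (i in idx) {
    expected <- naive_daq(labeled$text[i], lex)
    got <- if (labeled$is_daq[i]) {
      strsplit(labeled$daq_conditions[i], ";", fixed = TRUE)[[1]]
    } else character(0)
    expect_identical(sort(got), expected, info = labeled$text[i])
  }
})

test_that("appending any exclusion phrase flips a DAQ to negative", {
  cfg <- scenario_reference(scale = 0.02, seed = 32)
  gl <- generate_log(cfg, default_lexicon())
  daq_texts <- gl$log$text[vapply(gl$log$text,
                                  function(t) length(classify_daq(t, lex)) > 0,
                                  logical(1))]
  set.seed(32)
  picks <- sample(daq_texts, 1000, replace = TRUE)
  excl <- sample(lex$daq_exclude, 1000, replace = TRUE)
  flipped <- paste(picks, excl)
  for (i in seq_len(1000)) {
    expect_length(classify_daq(flipped[i], lex), 0)
  }
})

test_that("classification is invariant to case and interspersed punctuation", {
  mangle <- function(text) {
    toks <- strsplit(text, " ", fixed = TRUE)[[1]]
    toks <- vapply(toks, function(w) {
      if (runif(1) < 0.5) toupper(w) else w
    }, character(1))
    paste(toks, collapse = sample(c(", ", " - ", "  ", "! "), 1))
  }
  texts <- c("i was diagnosed with copd", "do i have gout",
             "chest pain when walking", "memorial hospital visiting hours",
             "i have lymphoma and night sweats")
  set.seed(33)
  for (t in texts) {
    for (k in 1:5) {
      m <- mangle(t)
      expect_identical(classify_daq(m, lex), classify_daq(t, lex), info = m)
      expect_identical(classify_symptoms(m, lex), classify_symptoms(t, lex))
      expect_identical(classify_hospital(m, lex), classify_hospital(t, lex))
    }
  }
})

test_that("label_queries flags DAQ, symptom and hospital queries jointly", {
  log <- make_log(
    list("u1", 0, "i have alpha fever and a rash"),
    list("u1", 1, "rash"),
    list("u2", 2, "city hospital parking"),
    list("u3", 3, "nothing to see")
  )
  lab <- label_queries(log, toy_lexicon())
  expect_equal(lab$is_daq, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(lab$daq_conditions[1], "alpha fever")
  # a DAQ can carry symptom hits at the same time
  expect_equal(lab$symptom_hits[1], "alpha fever:rash")
  expect_equal(lab$is_hospital, c(FALSE, FALSE, TRUE, FALSE))
})
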