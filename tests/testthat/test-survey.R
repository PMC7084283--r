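lex <- default_lexicon()

test_that("build_pairs produces verified real and sham pairs", {
  pairs <- build_pairs(lex, n_real = 104, n_sham = 156, seed = 81)
  expect_equal(nrow(pairs), 260)
  expect_equal(sum(pairs$is_real), 104)
  expect_equal(nrow(dplyr::distinct(pairs, condition, symptom)), 260)
  # exhaustive membership recheck against the lexicon
  real_set <- dplyr::select(lex$symptoms, condition, symptom)
  real_check <- dplyr::semi_join(pairs[pairs$is_real, ], real_set,
                                 by = c("condition", "symptom"))
  expect_equal(nrow(real_check), 104)
  sham_clash <- dplyr::semi_join(pairs[!pairs$is_real, ], real_set,
                                 by = c("condition", "symptom"))
  expect_equal(nrow(sham_clash), 0)
  # deterministic under a seed
  expect_identical(pairs, build_pairs(lex, 104, 156, seed = 81))
  expect_false(identical(pairs, build_pairs(lex, 104, 156, seed = 82)))
})

test_that("build_pairs boundaries and exhaustion errors", {
  all_real <- build_pairs(lex, n_real = 10, n_sham = 0, seed = 83)
  expect_true(all(all_real$is_real))
  expect_error(build_pairs(lex, n_real = 10000, n_sham = 0), "real pairs")
  expect_error(build_pairs(lex, n_real = 0, n_sham = 1e6), "sham pairs")
})

test_that("a perfect rater yields perfect accuracies", {
  pairs <- build_pairs(lex, n_real = 20, n_sham = 30, seed = 84)
  resp <- simulate_responses(pairs, n_raters = 2, recognition = 1,
                             sensitivity = 1, specificity = 1, seed = 84)
  agg <- glance(aggregate_survey(resp))
  expect_equal(agg$n_responses, 100)
  expect_equal(agg$recognition_pct, 100)
  expect_equal(agg$real_accuracy_pct, 100)
  expect_equal(agg$sham_accuracy_pct, 100)
})

test_that("aggregate_survey matches a hand-counted 12-response fixture", {
  resp <- tibble::tibble(
    pair_id = rep(1:4, each = 3),
    condition = rep(c("a", "a", "b", "b"), each = 3),
    symptom = "s",
    is_real = rep(c(TRUE, FALSE, TRUE, FALSE), each = 3),
    rater_id = rep(1:3, 4),
    recognized_condition = c(TRUE, TRUE, FALSE,  TRUE, FALSE, FALSE,
                             TRUE, TRUE, TRUE,   FALSE, FALSE, TRUE),
    associated = c(TRUE, FALSE, TRUE,  FALSE, FALSE, TRUE,
                   TRUE, TRUE, FALSE,  TRUE, FALSE, FALSE)
  )
  agg <- aggregate_survey(resp)
  o <- glance(agg)
  expect_equal(o$recognition_pct, 100 * 7 / 12)
  expect_equal(o$real_accuracy_pct, 100 * 4 / 6)   # real responses judged yes
  expect_equal(o$sham_accuracy_pct, 100 * 4 / 6)   # sham responses judged no
  bc <- tidy(agg)
  expect_equal(bc$recognition_pct[bc$condition == "a"], 100 * 3 / 6)
  # partition: real + sham denominators cover every response exactly once
  expect_equal(sum(resp$is_real) + sum(!resp$is_real), nrow(resp))
})

test_that("simulated rates recover the configured probabilities", {
  pairs <- build_pairs(lex, n_real = 104, n_sham = 156, seed = 85)
  resp <- simulate_responses(pairs, n_raters = 10, recognition = 0.86,
                             sensitivity = 0.86, specificity = 0.74,
                             seed = 85)
  o <- glance(aggregate_survey(resp))
  # binomial 3-sigma bands at n = 1040 real / 1560 sham / 2600 total responses
  expect_lt(abs(o$recognition_pct - 86), 3 * 100 * sqrt(0.86 * 0.14 / 2600))
  expect_lt(abs(o$real_accuracy_pct - 86), 3 * 100 * sqrt(0.86 * 0.14 / 1040))
  expect_lt(abs(o$sham_accuracy_pct - 74), 3 * 100 * sqrt(0.74 * 0.26 / 1560))
  expect_identical(resp, simulate_responses(pairs, 10, 0.86, 0.86, 0.74,
                                            seed = 85))
})

test_that("knowledge_rate_correlation is a Spearman on the two rate vectors", {
  recog <- c(90, 80, 70, 60, 50)
  rate <- c(5, 10, 15, 20, 25)
  res <- knowledge_rate_correlation(recog, rate)
  expect_equal(res$rho, -1)
  expect_true(knowledge_rate_correlation(rep(50, 5), rate)$undefined)
})
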