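lex <- toy_lexicon()

# Hand-enumerable fixture: u1 searches a symptom 30 days before the DAQ and
# later a hospital; u2's only symptom query shares the DAQ timestamp; u3
# self-identifies two conditions.
fixture_log <- function() {
  make_log(
    list("u1", 10, "bad headache all day"),
    list("u1", 40, "i have alpha fever"),
    list("u1", 41, "alpha clinic near me"),
    list("u2", 5.0, "i have beta pox cough"),   # symptom at the DAQ instant
    list("u3", 0, "i have alpha fever"),
    list("u3", 2, "diagnosed with beta pox")
  )
}

test_that("timelines capture first events and the strict before rule", {
  tl <- build_timelines(fixture_log(), lex)
  expect_equal(nrow(tl), 4)  # u1 alpha, u2 beta, u3 alpha, u3 beta
  u1 <- tl[tl$user_id == "u1" & tl$condition == "alpha fever", ]
  expect_true(u1$symptom_before_daq)
  expect_equal(as.numeric(difftime(u1$t_first_daq, u1$t_first_symptom,
                                   units = "days")), 30)
  expect_equal(u1$t_first_hospital, t_base + 41 * 86400)
  # same-timestamp symptom does not count as before
  u2 <- tl[tl$user_id == "u2", ]
  expect_equal(u2$condition, "beta pox")
  expect_equal(u2$symptom_query_count, 1L)
  expect_false(u2$symptom_before_daq)
  # two DAQ conditions -> two timelines
  expect_equal(sort(tl$condition[tl$user_id == "u3"]),
               c("alpha fever", "beta pox"))
  expect_true(all(is.na(tl$t_first_symptom[tl$user_id == "u3"])))
})

test_that("timelines are invariant to record order and global time shifts", {
  log <- fixture_log()
  tl <- build_timelines(log, lex)
  set.seed(41)
  shuffled <- log[sample(nrow(log)), ]
  expect_equal(build_timelines(shuffled, lex), tl)

  shifted <- dplyr::mutate(log, timestamp = timestamp + 86400 * 365 + 17)
  tl_s <- build_timelines(shifted, lex)
  expect_equal(tl_s$symptom_before_daq, tl$symptom_before_daq)
  expect_equal(tl_s$symptom_query_count, tl$symptom_query_count)
  expect_equal(
    as.numeric(difftime(tl_s$t_first_daq, tl_s$t_first_symptom, units = "days")),
    as.numeric(difftime(tl$t_first_daq, tl$t_first_symptom, units = "days"))
  )
})

test_that("adding a pre-DAQ symptom query only increases counts", {
  log <- fixture_log()
  tl <- build_timelines(log, lex)
  extra <- make_log(list("u2", 1, "coughing fits cough"))
  tl2 <- build_timelines(dplyr::bind_rows(log, extra), lex)
  u2_old <- tl[tl$user_id == "u2", ]
  u2_new <- tl2[tl2$user_id == "u2", ]
  expect_gte(u2_new$symptom_query_count, u2_old$symptom_query_count)
  expect_true(u2_new$symptom_before_daq)  # was FALSE, flips up only
})

test_that("symptom_query_count equals the sum of per-symptom counts", {
  cfg <- scenario_reference(scale = 0.01, seed = 42)
  gl <- generate_log(cfg, default_lexicon())
  tl <- build_timelines(gl$log, default_lexicon())
  sums <- vapply(tl$symptom_counts, function(sc) {
    if (is.null(sc)) 0L else as.integer(sum(sc$n))
  }, integer(1))
  expect_identical(as.integer(tl$symptom_query_count), sums)
})

test_that("cohort_filter applies the distinct-user threshold exactly", {
  tl <- tibble::tibble(
    user_id = c(sprintf("a%03d", 1:75), sprintf("b%03d", 1:74)),
    condition = rep(c("alpha fever", "beta pox"), c(75, 74))
  )
  expect_equal(cohort_filter(tl, 75), "alpha fever")
  expect_setequal(cohort_filter(tl, 74), c("alpha fever", "beta pox"))
  expect_equal(cohort_filter(tl[0, ], 75), character(0))
})

test_that("mean_symptom_queries averages pooled per-symptom counts", {
  sc <- function(...) tibble::tibble(symptom = letters[seq_along(c(...))],
                                     n = c(...), t_first = t_base)
  tl <- tibble::tibble(
    user_id = c("u1", "u2"), condition = "alpha fever",
    t_first_daq = t_base, t_first_symptom = t_base - 86400,
    symptom_before_daq = TRUE, symptom_query_count = c(3L, 1L),
    symptom_counts = list(sc(1, 2), sc(1)),
    t_first_hospital = as.POSIXct(NA, tz = "UTC")
  )
  expect_equal(mean_symptom_queries(tl), mean(c(1, 2, 1)))
  expect_true(is.na(mean_symptom_queries(tl[0, ])))
})
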