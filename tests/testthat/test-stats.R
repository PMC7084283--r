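test_that("condition_stats counts pre-diagnosis searchers on a hand fixture", {
  # 8 DAQ users for alpha fever, 3 of whom searched the symptom earlier
  rows <- list()
  for (i in 1:8) {
    u <- sprintf("u%d", i)
    rows[[length(rows) + 1]] <- list(u, 20, "i have alpha fever")
    if (i <= 3) rows[[length(rows) + 1]] <- list(u, 20 - i * 2, "rash")
  }
  tl <- build_timelines(do.call(make_log, rows), toy_lexicon())
  st <- condition_stats(tl)
  expect_equal(st$n_before, 3L)
  expect_equal(st$n_total, 8L)
  expect_equal(st$pct_before, 37.50)
  expect_equal(st$median_lag_days, 4)  # lags 2, 4, 6 days
})

test_that("aggregate_stats computes macro, pooled and cohort summaries", {
  st <- tibble::tibble(
    condition = c("a", "b"), n_before = c(10L, 30L),
    n_total = c(100L, 100L), pct_before = c(10, 30),
    median_lag_days = c(5, 5)
  )
  agg <- aggregate_stats(st)
  expect_equal(agg$macro_mean_pct, 20)
  expect_equal(agg$macro_sd_pct, sd(c(10, 30)))
  expect_equal(agg$pooled_pct, 20)
  expect_equal(agg$mean_cohort_size, 100)
  expect_equal(agg$se_cohort_size, 0)
  # equal percentages -> zero macro SD
  same <- dplyr::mutate(st, n_before = c(20L, 20L), pct_before = 20)
  expect_equal(aggregate_stats(same)$macro_sd_pct, 0)
  expect_error(aggregate_stats(st[1, ]), "at least 2")
})

test_that("the pooled rate is a convex combination of condition rates", {
  set.seed(61)
  for (k in 1:50) {
    m <- sample(2:8, 1)
    n_total <- sample(50:500, m)
    n_before <- rbinom(m, n_total, runif(m))
    st <- tibble::tibble(condition = letters[1:m], n_before = n_before,
                         n_total = n_total,
                         pct_before = 100 * n_before / n_total)
    agg <- aggregate_stats(st)
    expect_gte(agg$pooled_pct, min(st$pct_before) - 1e-9)
    expect_lte(agg$pooled_pct, max(st$pct_before) + 1e-9)
    expect_equal(agg$pooled_pct,
                 sum(st$pct_before * st$n_total) / sum(st$n_total))
  }
})

test_that("lag_rate_correlation follows monotone inputs and flags constants", {
  st <- tibble::tibble(condition = c("a", "b", "c"),
                       n_before = c(1L, 2L, 3L), n_total = c(10L, 10L, 10L),
                       pct_before = c(10, 20, 30),
                       median_lag_days = c(1, 2, 3))
  expect_equal(lag_rate_correlation(st)$rho, 1)
  const <- dplyr::mutate(st, pct_before = 15)
  expect_true(lag_rate_correlation(const)$undefined)
  withNA <- dplyr::bind_rows(
    st, tibble::tibble(condition = "d", n_before = 0L, n_total = 10L,
                       pct_before = 0, median_lag_days = NA_real_))
  expect_warning(res <- lag_rate_correlation(withNA), "dropped")
  expect_equal(res$n, 3)
})

test_that("pct_increase reproduces the severity-stratum comparison", {
  expect_equal(round(pct_increase(19.13, 16.81)), 14)
  expect_equal(pct_increase(19.13, 16.81), 100 * (19.13 - 16.81) / 16.81)
  expect_equal(pct_increase(10, 10), 0)
})

test_that("msr_stratify partitions conditions and pools stratum rates", {
  lex <- toy_lexicon()  # min MSR: alpha 2, beta 5, gamma none
  st <- tibble::tibble(
    condition = c("alpha fever", "beta pox", "gamma flu"),
    n_before = c(30L, 10L, 5L), n_total = c(100L, 100L, 50L),
    pct_before = c(30, 10, 10), median_lag_days = c(3, 3, 3)
  )
  ms <- msr_stratify(st, lex, threshold = 2)
  expect_s3_class(ms, "msr_strata")
  expect_equal(sort(tidy(ms)$group), c("excluded", "high_msr", "low_msr"))
  expect_equal(ms$rate_low_pct, 30)   # 30/100
  expect_equal(ms$rate_high_pct, 10)  # 10/100
  expect_equal(ms$pct_increase, 200)
  expect_false(ms$flagged)
  # macro option averages percentages instead of pooling counts
  ms_macro <- msr_stratify(st, lex, threshold = 2, rates = "macro")
  expect_equal(ms_macro$rate_low_pct, 30)
  expect_equal(ms_macro$rate_high_pct, 10)
  expect_error(msr_stratify(st, lex, threshold = 0), "1..10")
})

test_that("msr_stratify flags when every condition lacks a rank", {
  st <- tibble::tibble(
    condition = "gamma flu", n_before = 5L, n_total = 50L,
    pct_before = 10, median_lag_days = 3
  )
  ms <- msr_stratify(st, toy_lexicon())
  expect_true(ms$flagged)
  expect_true(is.na(ms$pct_increase))
  expect_equal(tidy(ms)$group, "excluded")
})
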