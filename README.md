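# prediag

Infodemiology toolkit for a question that matters to anyone designing
search-based disease screening: **how often do people search the web about
their symptoms before a clinician formally diagnoses them?**

`prediag` answers it from raw query logs with a fully rule-based,
lexicon-driven pipeline:

* **DAQ detection** — a *diagnosis ascertainment query* is a query matching
  an inclusion phrase ("i have", "diagnosed with") and a condition alias
  while containing none of twelve exclusion phrases ("do i have",
  "i think i have", "wife", "dog", ...). Matching is contiguous
  token-subsequence matching on normalized text, so "hospitality" never
  matches "hospital" and "i haven't" never matches "i have".
* **Per-user timelines** — first DAQ, first symptom query, per-symptom
  query counts, first hospital/clinic query, per (user, condition).
* **Pre-diagnosis rates** — per condition, the fraction of DAQ users whose
  first relevant symptom query *strictly* preceded their first DAQ:

  `pct_before = 100 * n_before / n_total`

  aggregated both macro (unweighted mean across conditions, with sample SD)
  and pooled (`100 * sum(n_before) / sum(n_total)`).
* **Interpretation layers** — Spearman rank correlation (midranks; exact
  permutation p-values below n = 10, t-approximation above) between rates
  and symptom-to-DAQ lead times; stratification by minimum Medical Severity
  Rank (MSR 1 = most urgent) with the percent increase
  `100 * (rate_low_msr - rate_high_msr) / rate_high_msr`; hospital-query
  lag timing (signed lags, window fractions, day histogram) validating that
  DAQs happen around the true diagnosis date.
* **A recognition survey design** — real versus verified sham
  condition–symptom pairs, simulated raters, response-level accuracy rates,
  and the recognition-versus-query-rate correlation.
* **A seeded synthetic log generator** — emulates cohorts, pre-diagnosis
  probabilities, lead-time distributions, geometric query repetition,
  hospital-query jitter, excluded-phrase distractors and screened background
  noise, with an exact ground-truth table, so every stage is testable
  without proprietary search data.

A bundled lexicon covers 20 conditions (gout, lymphoma, heart failure,
Parkinson disease, ...) with aliases and symptom synonym phrases, and
bundled reference tables carry the per-condition counts observed in a
year-long archival search-log study for reproduction and for realistic
synthetic scenarios.

## Worked example

```r
library(prediag)

lex <- default_lexicon()
cfg <- scenario_reference(scale = 0.1, seed = 42)   # ~1,240 cohort users
gl  <- generate_log(cfg, lex)

tl <- build_timelines(gl$log, lex)
st <- condition_stats(tl, cohort_filter(tl, min_users = round(75 * 0.1)))
head(st, 3)
#> # A tibble: 3 × 5
#>   condition                                 n_before n_total pct_before median_lag_days
#> 1 angina pectoris or coronary heart disease       30      78      38.5            33.4
#> 2 bells palsy                                      0      17       0              NA
#> 3 bladder cancer                                   5      30      16.7            10.8

aggregate_stats(st)[, c("macro_mean_pct", "macro_sd_pct", "pooled_pct")]
#>   macro_mean_pct macro_sd_pct pooled_pct
#> 1         13.733     10.38713   14.96764

lag_rate_correlation(st)
#> Spearman rank correlation: rho = 0.9205, p = 4.363e-07 (t approximation), n = 16
```

Reading the numbers: in this reduced synthetic scenario 38.5% of the 78
coronary-disease users searched a symptom (median 33 days) before first
stating their diagnosis, a typical condition sits near 13.7% (the pooled
patient-level rate is 15.0%), and conditions with longer symptom lead
times are searched more (rho = 0.92) — the association the generator
builds in. The survey side works the same way:

```r
pairs <- build_pairs(lex, n_real = 104, n_sham = 156, seed = 42)
resp  <- simulate_responses(pairs, n_raters = 10, seed = 42)
glance(aggregate_survey(resp))
#>   n_responses recognition_pct real_accuracy_pct sham_accuracy_pct
#> 1        2600              86              85.2              76.0
```

`plot_condition_rates()`, `plot_lag_histogram()` and `autoplot()` methods
render the standard figures; `tidy()`/`glance()` turn fitted objects into
tibbles; `run_pipeline()` wires everything into a report bundle (TSV
tables, JSON summary, run manifest) from a log file or in-memory tibble.

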