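---
title: "Measuring pre-diagnosis symptom search in query logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring pre-diagnosis symptom search in query logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prediag)
library(dplyr)
```

## The question and the measurement model

Many people search the web about their symptoms before a clinician ever
names their disease. If that behaviour is common enough, search queries are
a plausible substrate for early-warning screening systems; if it is rare or
wildly uneven across diseases, such systems can only ever reach a small
slice of patients. `prediag` implements a measurement pipeline that puts a
number on this behaviour using nothing but a raw query log (user id,
timestamp, query text) and a lexicon of conditions, symptom phrases, and
hospital terms.

The measurement proceeds in three rule-based steps:

1. **Self-identification.** A *diagnosis ascertainment query* (DAQ) is a
   query that contains an inclusion phrase ("i have", "diagnosed with") and
   a surface alias of a condition, and none of twelve exclusion phrases
   ("do i have", "i think i have", "wife", "dog", ...) that mark
   hypothetical or third-party phrasings. Users with at least one DAQ for a
   condition form that condition's cohort; their first DAQ timestamp is the
   proxy for the diagnosis date.
2. **Pre-diagnosis symptom attribution.** For each cohort member we find
   their first query matching any surface phrase of any symptom term of the
   condition. The user counts as a *pre-diagnosis searcher* when that first
   symptom query is strictly earlier than the first DAQ — a tie at the same
   second does not count, so a single query that both states the diagnosis
   and names a symptom is never self-evidence.
3. **Aggregation.** Per condition we report `n_before / n_total` and its
   percentage; across conditions we report both the macro (unweighted) mean
   of percentages and the pooled ratio of summed counts. These answer
   different questions — "how does a typical condition behave" versus "how
   does a typical patient behave" — and can differ by a full percentage
   point on realistic inputs, so both are always exposed.

Two companion analyses interpret the rate. The *lead-time correlation*
(Spearman, across conditions) asks whether conditions whose symptoms
precede diagnosis by longer are searched more. The *severity
stratification* labels each condition with the lowest (most worrying)
Medical Severity Rank among its symptoms — MSR runs from 1 (requires
immediate urgent care) to 10 (can be disregarded) — and compares pooled
rates for conditions with minimum MSR at or below 2 against the rest;
conditions with no ranked symptom are excluded rather than imputed. The
*hospital-lag analysis* validates the DAQ-as-diagnosis-proxy assumption: if
DAQs happen around true diagnosis, first hospital/clinic queries should
cluster tightly around first DAQs, which is summarised by signed lags
(negative = hospital query first), symmetric window fractions, and a
whole-day histogram.

## Matching rules and their edge cases

All matching is contiguous token-subsequence matching on normalized text
(lowercased, punctuation outside letters/digits/apostrophes stripped,
whitespace collapsed). This single choice resolves several traps:
"hospitality" never matches "hospital", "i haven't" never matches "i have",
while "do i have copd" does contain the tokens "i have" — which is exactly
why the exclusion list, not the matcher, is responsible for rejecting it.
The inclusion phrase and the alias may occur anywhere in the query in any
order, because self-identification phrasings vary ("recently diagnosed
with severe gout"). A query matching aliases of several conditions is a
DAQ for each; cohorts are built independently per condition. Only the
twelve listed exclusion phrases are applied; further exclusions belong in
the lexicon file, not in code.

The bundled lexicon (`default_lexicon()`) covers 20 conditions chosen for
having evident symptoms and not being systematically screened, with a
modest set of surface synonyms per symptom term. Its fidelity has a known
consequence: gout's symptom list contains the bare word "pain", so any
query mentioning pain is a gout-symptom query. That is deliberate — symptom
lists are data, and sensitivity/specificity trade-offs are made in the
lexicon, not the matcher. MSR values are not bundled because they are
external measurements; `msr_stratify()` on the bundled lexicon therefore
returns a flagged result until the user supplies ranks.

## The Spearman implementation

Rank correlation is computed on midranks (average ranks under ties) with
the product-moment formula. For `n >= 10` the two-sided p-value uses the
t-approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`; below 10 the full
permutation distribution of one ranking is enumerated (at most 9! = 362,880
permutations), which is exact, deterministic, and valid under ties.
Constant vectors leave the coefficient undefined and are flagged rather
than raising an error, because constant per-condition rates are a
legitimate (if degenerate) outcome on small synthetic runs. The tests hold
the implementation to the reference `stats::cor`/`cor.test` results to
1e-12 on the coefficient.

## What the synthetic generator emulates — and what it does not

Real query logs of this kind are proprietary, so the package ships a seeded
generator (`synth_config()`, `generate_log()`) that emulates the
*statistical structure* the pipeline depends on:

* per-condition cohorts in which every user issues one templated DAQ at a
  uniformly drawn diagnosis day (random second within the day);
* with probability `p_pre`, one symptom term queried `1 + Geometric(p)`
  times, the first occurrence a log-normal lead time before the DAQ and
  always at least one second earlier, so the strict-inequality rule is
  exercised deterministically;
* with probability `p_hospital`, a hospital query at the diagnosis time
  plus Normal(0, sd) jitter in days, mixed with a point mass on the
  diagnosis date itself;
* distractor users who issue only excluded phrasings ("do i have X", "my
  husband was diagnosed with X"), which must produce zero timelines;
* Poisson background noise drawn from a neutral phrase pool that is
  screened at build time so no lexicon phrase occurs in it — ground truth
  is therefore exact, and the generator's truth table is asserted to match
  the pipeline's output user for user.

`scenario_reference()` pins the generator to the study conditions the
package models: the 20 bundled cohort sizes (12,366 users at scale 1),
`p_pre` equal to the observed per-condition percentages, lead-time medians
set to `100 * p_pre` days so the positive rate–lead-time association is
built in by construction, geometric repeat parameter `1/1.7` (reproducing
the observed mean of 1.7 queries per queried symptom), hospital-query
probability 0.6 (between the observed 55–65% per-condition rates), and
hospital jitter SD 17 days with a 0.19 same-day mass. The jitter pair was
solved once from the observed window masses (67% within ±14 days, 47%
within ±7, 19% same-day) under the point-mass-plus-normal model:
`0.19 + 0.81 * P(|N(0, 17)| <= 14) ≈ 0.67` and
`0.19 + 0.81 * P(|N(0, 17)| <= 7) ≈ 0.45`.

The generator deliberately does **not** model realistic query language
(queries are short templated phrases), phrase ambiguity between background
noise and the lexicon, seasonality, session structure, demographics, or
users whose diagnosis predates the observation window. Passing tests
therefore certify the *pipeline arithmetic and rules* on data whose ground
truth is known exactly; they do not certify recall of the lexicon on real,
colloquial query text, which is bounded by lexicon coverage alone.

## Numerical choices and degenerate inputs

* "Before" is strict at second resolution; lags are measured in fractional
  days (seconds / 86,400); medians use the midpoint of the middle two for
  even counts.
* Per-condition percentages are reported to 2 decimals; the severity
  percent increase `100 * (rate_low - rate_high) / rate_high` is rounded to
  the nearest integer for reporting; other rates are kept unrounded.
* The cohort filter defaults to 75 distinct DAQ users per condition and
  should be scaled together with synthetic cohort sizes (the replicated
  coupling check uses `round(75 * scale)`).
* Conditions with zero pre-diagnosis searchers have no median lag; the
  lag-rate correlation drops them with a warning rather than failing.
* Empty strata, all-excluded MSR sets, constant correlation inputs, and
  hospital-free cohorts all return flagged/NA results, never errors; an
  empty query log or a log without DAQs is an error, because it indicates a
  broken input rather than a degenerate-but-valid one.
* Timestamp ingestion is strict by default (abort with line numbers);
  lenient mode drops bad records with a warning.

## Survey module

The recognition survey design is mirrored synthetically: `build_pairs()`
draws real condition–symptom pairs from the lexicon and sham pairs by
matching a condition with a symptom and verifying non-membership (both by
canonical name and by any shared surface phrase — a sham pair must not be
accidentally true under a synonym). The sham space is enumerated and
sampled without replacement, which is distributionally identical to
rejection sampling but finite and able to fail loudly when too few valid
pairs exist. `simulate_responses()` models raters with a recognition
probability and an association sensitivity/specificity;
`aggregate_survey()` reports response-level rates, and
`knowledge_rate_correlation()` relates per-condition recognition to the
pre-diagnosis rate (the interesting sign is negative: less recognizable
symptom associations attract more searching).

## Problem sizes used by the checks

The bundled checks run the full-scale scenario once (12,366 cohort users,
roughly 50,000 queries, a few seconds on one core) for parameter recovery —
estimated per-condition rates are required to sit inside exact 95% binomial
intervals of the configured probabilities for at least 18 of 20 conditions
— and twenty replicates at scale 0.3 for the lead-time coupling, requiring
`rho > 0.5` in at least 18 of 20 seeded runs. The printed study aggregates
(15.49% macro mean, SD 8.4; mean cohort 618, SE 189; the per-condition,
hospital, severity, and survey figures) are recomputed from the bundled
reference counts through the same aggregation functions used on synthetic
data.

## Known limitations

* Lexicon coverage bounds recall: colloquial symptom descriptions missing
  from the phrase lists are invisible, which biases measured rates
  downward on real text.
* The first DAQ is only a proxy for the diagnosis date; the hospital-lag
  analysis quantifies, but cannot remove, that approximation.
* A finite observation window truncates lead times: users who searched
  their symptoms before the window began are counted as non-searchers.
* Self-identifying users are a self-selected subpopulation; nothing in the
  pipeline corrects for that selection.
* The pooled reference counts carry small internal inconsistencies (a few
  printed percentages and stratum rates do not exactly equal their printed
  count ratios); the package computes from whichever representation it is
  given and does not attempt to reconcile them.

## A worked example

```{r example, eval = FALSE}
lex <- default_lexicon()
cfg <- scenario_reference(scale = 0.1, seed = 42)
gl <- generate_log(cfg, lex)

tl <- build_timelines(gl$log, lex)
keep <- cohort_filter(tl, min_users = round(75 * 0.1))
st <- condition_stats(tl, keep)
aggregate_stats(st)
lag_rate_correlation(st)

plot_condition_rates(st)
plot_lag_histogram(lag_histogram(tl,
  conditions = c("endometrial cancer", "esophageal cancer", "lymphoma")))
```
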