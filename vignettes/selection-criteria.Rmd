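---
title: "Selection criteria for non-systematic adverse events: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection criteria for non-systematic adverse events: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aeselect)
```

## The problem

Adverse events (AEs) collected *non-systematically* in a randomized trial —
spontaneous, unprompted participant reports — produce long listings with
hundreds of distinct AE terms, most of them rare. A clinical study report
(CSR) typically lists all of them; journal articles and other public
sources usually do not. Instead, report authors apply a **selection
criterion**: a rule deciding which AE terms make it into the report.
Because the rule conditions on the trial's own results, it is a
reporting-bias mechanism: a systematic reviewer who only sees the public
sources works from a results-dependent subset of the evidence.

`aeselect` formalizes such criteria, applies them to per-arm AE frequency
tables, measures how much of a trial's AE profile survives each rule, and
quantifies by simulation what criterion-based censoring does to a
meta-analysis of harms.

## The data model

An `ae_table` holds one trial: arms with safety-population sizes `n` and
an `is_active` flag (the test-intervention arm(s) versus placebo), and for
each distinct AE term the number of participants with at least one event
per arm. Three modeling commitments deserve emphasis:

* **Counts are participants, not events.** A participant with three
  episodes of dizziness contributes 1 to the dizziness cell.
* **"Number of AEs" always means number of distinct AE types.** All
  percent-reported quantities are fractions of the distinct terms stored.
* **Only observed terms are stored.** A term no participant experienced
  does not appear, just as it would not appear in a CSR listing. The
  denominator of every percent-reported figure is therefore the count of
  terms with at least one affected participant.

The per-arm denominator is caller-supplied rather than derived: published
sources do not always say whether they used randomized or safety
populations, so the engine stays agnostic and uses whatever `n` the data
provides (conventionally the safety population).

## Criteria and their semantics

A criterion has three components, written in a compact DSL:

```
thr=<number>%[;scope=<any|active|all>][;diff=<none|higher|ratio>=<r>>]
```

* **Threshold** (`thr`): inclusive — "occurring in ≥ 2%" passes at exactly
  2%. Every criterion observed in real sources is phrased with "≥"; a
  `strict = TRUE` switch (default off) provides the `>` variant in case a
  source meant the exclusive form.
* **Scope** (`scope`): `any` thresholds the maximum per-arm proportion;
  `active` the pooled test-intervention proportion; `all` the proportion
  among all participants combined. With multiple active dose arms,
  `active` pools them — reports saying "drug-treated patients" might
  alternatively mean a single (e.g. highest) dose arm, which can be
  emulated by flagging only that arm active. `all` includes the placebo
  arm, reading "all trial participants" literally.
* **Difference rule** (`diff`): `none`; `higher`, meaning the pooled
  active proportion strictly exceeds the pooled comparator proportion
  (ties carry no signal, so they fail); or `ratio>=r`, meaning the active
  proportion is at least `r` times the comparator proportion (`r = 2`,
  "at least twice as frequent", is the only observed value, but any
  `r > 1` is accepted). When the comparator proportion is zero, any
  positive active proportion passes the ratio clause — "at least twice
  zero" is vacuously exceeded — while zero against zero fails, since a
  term nobody experienced in either pooled group carries no signal.

Comparisons are **exact**: `count/n >= pct/100` is evaluated as
`count*100 >= pct*n` in integer arithmetic, and the difference rules
cross-multiply the pooled fractions, so no floating-point rounding can
flip a boundary case. Some real report authors plausibly thresholded the
*rounded* percentages printed in their tables; `rounded_percents = TRUE`
(default off) reproduces that behaviour by rounding every proportion to a
whole percent (half-up) before comparison. For example 15/1000 = 1.5%
fails an exact ≥ 2% test but passes the rounded one.

The observed component sets — thresholds 1%, 2%, 3%, 5%, 10%; all three
scopes; the three difference rules — cross into the canonical grid of
5 × 3 × 3 = 45 combined criteria (`build_grid(observed_components())`),
ordered threshold-major, then scope (`any`, `active`, `all`), then diff
(`none`, `higher`, `ratio`). The order is arbitrary but fixed, so grid
rows, heat-map rows and CSV outputs are stable across runs and platforms.

## The heat map and discrepancy checks

`criteria_heatmap()` evaluates every grid criterion on every trial and
records the percent of the trial's distinct AE terms that would be
reported — one cell per (criterion, trial). Cells are monotone in the
components: raising the threshold, narrowing the scope from `any` to a
pooled scope, or adding a difference rule can only shrink the reported
set. These orderings are enforced as property tests.

`check_discrepancies()` compares what a source *did* report against what
its *stated* criterion implies: terms meeting the criterion but missing
from the source are under-reported; reported terms failing it are
over-included; reported terms absent from the full table are flagged
unknown rather than treated as errors, since public sources sometimes
name AEs the CSR codes differently.

## The synthetic-data generator

`synthetic_config()` + `simulate_trial()`/`simulate_trials()` emulate
non-systematically collected AEs well enough to exercise every criterion:

* many distinct terms (default 300) with a **long-tailed background
  incidence** — log-uniform between 0.05% and 20% by default, or a
  Pareto tail via `power_law()`. The defaults put most terms below every
  observed threshold, matching the situation where a CSR lists hundreds
  of AEs but a journal article lists a handful;
* a configurable **elevated subset** (default 10% of terms) whose
  active-arm incidence is the background times a **risk ratio** (default
  2), capped at 1;
* default **arm sizes of 200 per arm**, the order of magnitude of the
  placebo-controlled trials that motivated the design;
* independent `Binomial(n_arm, incidence)` draws per term and arm, with
  terms nobody experienced dropped before storage.

Seeding is layered: stream 0 of a master seed draws the latent truth
(incidences and the elevated set), stream *i* draws trial *i*'s counts.
Trials of one simulated drug therefore share a truth, counts are
independent across trials, adding trials never changes earlier ones, and
`simulate_trials(cfg, 1, s)` reproduces `simulate_trial(cfg, seed = s)`.
The generated truth is attached to each table (`attr(x, "ground_truth")`),
so calibration checks can compare observed against analytic quantities —
e.g. the expected number of stored terms,
$\sum_j \bigl(1 - \prod_{\text{arms } a} (1 - p_{ja})^{n_a}\bigr)$.

What the generator does **not** model: correlation between AE terms
within a participant, differential ascertainment between arms, visit
schedules, dropout, term-coding variation, or time windows. Passing tests
on this generator show that the selection logic and the bias mechanics
are correct; they do not show that real trials' AE profiles are binomial
or independent.

## The meta-analysis bias experiment

The harms-meta-analysis model is deliberately minimal. For one AE term
across $k$ trials, stratum $i$ contributes active events/total
$(a_i, n_{1i})$ and comparator events/total $(c_i, n_{0i})$, pooled with
the fixed-effect Mantel–Haenszel risk ratio

$$\widehat{RR}_{MH} \;=\; \frac{\sum_i a_i\, n_{0i} / N_i}{\sum_i c_i\, n_{1i} / N_i},
\qquad N_i = n_{1i} + n_{0i},$$

implemented directly from this formula. The risk-ratio scale (not odds
ratio) matches how criteria themselves are phrased ("twice as frequent").
No continuity corrections are applied: zero cells contribute zero to the
sums, a zero denominator with a positive numerator yields `Inf`, and
all-zero strata yield `NA` — the estimate is reported as undefined rather
than patched, because any correction would embed an analysis choice the
selection mechanism under study says nothing about. No meta-analytic
estimator is canonical for this problem; the fixed-effect MH estimator
was chosen as the minimal standard tool, and `metafor::rma.mh` serves as
an independent cross-check in the test suite, never as the
implementation.

`bias_experiment()` then contrasts two analysts per Monte-Carlo
replicate:

1. the **complete-evidence** analyst pools every trial (a term absent
   from a trial contributes a zero stratum);
2. the **selective** analyst sees each trial only through a selection
   criterion (`simulate_reporting()` censors each table to its passing
   terms) and pools a term only over the trials that reported it —
   trials not reporting the term are *omitted*, availability-bias style,
   because that is all a reviewer of journal articles can do.

Two structural facts anchor the experiment. With a zero threshold the
selective corpus equals the complete one, so the two pooled estimates
agree *exactly*, every replicate — a sharp no-selection null the test
suite asserts with equality, not tolerance. And under the global null
(risk ratio 1, no elevated terms), criteria with a `higher` or `ratio`
clause report a term precisely in the trials where it happened to look
worse on drug, so the selective pooled log-RR is positive on average;
the direction is a theorem of the conditioning, and the magnitude is a
simulation output, not a reproduction target.

## Problem sizes and numerical choices

The shipped checks use sizes chosen to make Monte-Carlo error small
relative to the effects under study while keeping a full run on a laptop
in minutes: 200 random tables of ≤ 10 terms for the brute-force oracle
sweep over all 45 criteria; 200 resampled trials for the stored-term
calibration (agreement required within 3 Monte-Carlo standard errors);
200 replicates of 20 trials for the null-bias direction (one-sided t-test
at α = 0.01); 50 replicates of 8 trials for the rare-AE visibility
curves. Percent-reported values are computed exactly and only rounded
(to 1 decimal) at CSV export.

## Limitations

* The engine treats AE terms as opaque strings (trim/case-insensitive);
  it does not code or group terms, so criteria applied before versus
  after term grouping are not comparable.
* Tables are assumed time-resolved already; no time-window extraction.
* The bias experiment equalizes arm sizes across simulated trials; with
  strongly varying sizes the MH weights differ but the selection
  mechanics are unchanged.
* Reproducing the published per-trial counts for the quetiapine trial
  with 316 CSR AE types requires the study's deposited per-arm table
  (Dryad doi:10.5061/dryad.mp26fb1), which cannot ship with the package;
  the corresponding check reads it from
  `options(aeselect.calabrese_csv = ...)` when available.
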