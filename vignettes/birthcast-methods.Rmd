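---
title: "Forecasting regional births from screening-registered due dates: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting regional births from screening-registered due dates: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(birthcast)
```

## The forecasting model

birthcast forecasts the weekly number of births in a region from the
expected dates of birth (EDDs) registered at routine first-trimester
screening. The EDD is itself a prediction — last menstrual period
corrected by crown–rump length ultrasound, anchored at gestational week
40 — so a due-date census must be smeared over the surrounding weeks to
become a birth forecast. The smearing kernel is a discrete gestational
offset distribution `p(o)`: the probability that delivery occurs `o`
whole ISO weeks after the due-date week, with default support
`o ∈ [−17, +5]` (delivery between gestational weeks 23 and 45).

Each registered pregnancy in due-date week `s` is assigned independently
to birth week `s + o` with probability `p(o)`. The weekly tally is a sum
of independent Bernoulli variables — Poisson-binomial — so its exact
moments are

$$\mu_w = \sum_s n_s\,p(w-s), \qquad
  \sigma^2_w = \sum_s n_s\,p(w-s)\,\{1-p(w-s)\}.$$

Two implementations coexist deliberately. `analytic_forecast()` evaluates
these closed forms; `mc_forecast()` simulates the assignment, by default
with 1000 replicates, and summarises replicate tallies into a mean, SD and
confidence band. The Monte Carlo route is the operational one (it extends
naturally to percentile intervals and replicate retention); the analytic
route is the independent oracle the test suite holds it against, and the
two must agree to Monte Carlo error on every input.

**Replication unit.** Replication is per whole series: one replicate
redistributes every source week once with independent draws. Replicating
week-by-week with independent draws is statistically identical for
per-week moments; the whole-series form has simpler provenance (one seed,
one replicate count) and allows joint quantities across weeks if
replicates are retained.

**Assumptions worth stating.** Offsets are i.i.d. across pregnancies and
independent of calendar time, municipality, parity and multiplicity; the
due-date census within covered municipalities is complete from ~29 weeks
before the due date; and the offset distribution used for forecasting
matches the one generating the births. Violations show up directly as
miscalibration of the band or bias in the mean.

## Key parameters

| parameter | default | units | rationale |
|---|---|---|---|
| PMF support | −17..+5 | weeks | deliveries at gestational weeks 23–45; configurable per PMF file |
| `n_reps` | 1000 | replicates | MC error on means ≈ σ/√1000 ≈ 3% of σ, negligible against weekly noise |
| `ci_level` / method | 0.95, normal | — | band reported operationally; percentile variant available when replicates are retained |
| coverage threshold | 55 | % | representativeness floor for including a municipality, while keeping data loss low |
| registration lead | 29 | weeks | booking bloods at ~week 11 of a 40-week term |
| horizon | 13 | weeks | widest horizon with complete registrations: a target week needs due dates up to 17 weeks after it (preterm reach), and 29 − 17 = 12–13 weeks ahead is the last fully registered target |
| bin width | 2 | weeks | operational default: the granularity/stability trade-off chosen by planning stakeholders |

The true national gestational-length distribution is not openly
redistributable, so the shipped PMF (`synthetic_gestation_pmf()`,
`pmf_id = "synthetic-standin-v1"`) is a synthetic stand-in: mode at offset
0, ~7% preterm mass below −3, a thin post-term tail, slightly negative
mean. It reproduces the *shape class* of national statistics, not any
registry's exact values; analyses with access to registry data should
override it via `read_gestation_pmf()`. Every forecast records the PMF id
used.

## Conventions and numerical choices

* **Weeks** are ISO-8601 (Monday start), keyed internally by the Monday
  date so week arithmetic is plain date arithmetic and immune to
  year-boundary ambiguity. The week convention is a package choice; any
  consistent convention gives the same science.
* **Coverage percentages** are rounded half-away-from-zero to integers,
  and the inclusion comparison is `coverage_pct >= threshold` ("at least
  55%"). Pooled multi-year counts are used per municipality (per-year
  coverage is not computed); pooling is what the bundled regional table
  reflects.
* **PMF validation**: probabilities must sum to 1; deviations below 1e−9
  are treated as floating-point dust and renormalized, anything larger is
  rejected so a corrupted distribution file fails loudly.
* **Binned SDs** combine as √(Σ sd²) under an independence approximation
  across weeks. This is exact for the analytic model only when the weeks
  being summed share no source weeks; in general adjacent target weeks are
  negatively correlated (a pregnancy lands in exactly one week), so the
  RSS rule slightly over-states the binned SD, making binned bands mildly
  conservative. The approximation is flagged in the `sd_method`
  attribute.
* **Completeness**: a target week is complete only if every contributing
  due-date week lies inside the data range (at the series edges) and
  inside the registrable window given the reporting date (the horizon
  rule). Incomplete weeks are flagged, never silently reported — they
  systematically undershoot realized births.
* **Degenerate inputs**: empty record sets aggregate to an empty series;
  constant series are rejected by the correlation (undefined) rather than
  returning NA; a zero-mean actual series cannot be normalized;
  `sd = 0` forces `ci_low = ci_high = mean` under the normal method.

## Validation protocol

Provider-based forecasts and registry birth counts live on different
scales (partial coverage), so the actual series is rescaled by the ratio
of means over the common window before comparison; the factor is reported,
and an alternative that inflates the forecast by 1/coverage is available.
Pearson r is computed per bin width on identically anchored bins, and the
weekly fraction of (scaled) actuals inside the 95% band is recorded.
Pearson r is invariant under the positive affine normalization, so the
correlation results do not depend on the scaling choice — only the
coverage fraction does.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` draws weekly pregnancy intake as Poisson around a
sinusoidally modulated rate, assigns due dates a uniform weekday within
the week, realizes birth weeks through the offset PMF, and thins
observations per municipality by a coverage fraction (coverage above 1 is
realized as extra observed-only registrations, emulating deliveries
credited to another municipality in the registry). Defaults — 156 weeks,
110 pregnancies/week regionally, amplitude 0.10, coverage fractions
0.70–1.10 — are sized once to resemble a mid-sized Dutch region and its
published coverage range.

It deliberately omits: maternal covariates (age, parity, multiplicity),
secular trends and shocks (pandemic birth waves), week-of-year effects
beyond a single sinusoid, EDD revision after later ultrasounds, and any
mismatch between the forecasting PMF and the generating PMF. Consequently,
passing calibration tests on synthetic cohorts demonstrates *internal
consistency* — the engine, normalization and intervals do what the model
claims — not that real registry data meet the model's assumptions. On real
data the published experience is that weekly correlation is modest and
improves substantially with 2–3-weekly binning; reproducing specific real
values requires the restricted microdata and is out of scope here.

## Problem sizes used by the checks

The test-suite and acceptance-script simulations use cohorts of 60–156
weeks at 60–110 pregnancies/week, 100–1000 Monte Carlo replicates, 20
randomized oracle inputs, and 30–50 validation replicates; these sizes
give binomial/Monte-Carlo standard errors comfortably inside the asserted
tolerances (e.g. 4 SE bounds for means, [0.8, 1.25] for SD ratios at 1000
replicates) while keeping a full run in the order of seconds.

## Known limitations

* The stand-in PMF is synthetic; operational use requires a
  registry-derived distribution.
* Coverage filtering assumes the provider's share of a municipality is
  stable over the study window; pooled counts cannot detect drift.
* The normal band can dip below zero for near-empty weeks at the series
  edges; those weeks are flagged incomplete, and the percentile method
  avoids the artifact when replicates are retained.
* No autoregressive or machine-learning correction is attempted: at a few
  years of weekly regional data such models are under-determined, and the
  due-date census already carries most of the predictable signal.
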