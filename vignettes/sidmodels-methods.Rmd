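---
title: "Methods: impending-death sign statistics and OR-rule models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: impending-death sign statistics and OR-rule models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sidmodels)
```

## The problem and the data model

Hospitalised noncancer patients entering the dying phase are observed by
nursing staff roughly every 12 hours, from the point at which oral intake
collapses until death or a discontinuation criterion (eating more than half
of each meal for two consecutive days, 60 days of observation, discharge,
ventilation, artificial nutrition, or a new cancer diagnosis). At each
observation 11 binary physical signs are charted and vitals are recorded. A
12th predictor, shock index (heart rate / systolic blood pressure) above
1.0, is derived from the vitals.

Time is stored in hours from a per-cohort origin; days in reports are
hours/24. The 12-h grid and the 24/72/168-h horizons are then all integral.
A sign flag can be present, absent, or *missing* — a form that was not
filled. Missing is skipped, never read as absent: a sign's first event
requires an explicit "present". Only the first appearance defines the event;
later disappearance is ignored, because the rule statistic references a
single event time per predictor. The analysis population for every rule
statistic is the decedents; censored patients are excluded with a warning.

### Onset timing

Onsets are timed at the first positive observation, not at an interval
midpoint: truth is interval-censored on the 12-h grid, but the source design
reports observation-time onsets, and modelling the censoring would change
every downstream quantity by at most half an observation interval. This
shows up as a downward bias of up to 0.5 day in empirical onset medians, and
the generator's calibration tolerances account for it.

## Per-sign statistics

**Prevalence within 72 h of death.** Two readings exist. Counting patients
whose *first* event falls inside the window is, for decedents, algebraically
the same number as the 72-h mortality numerator (death − first event ≤ 72 h
is the identical condition), yet the published per-sign table reports
distinct values (e.g. 38 prevalent vs 29/38 dying within 72 h of onset). The
two columns are therefore measuring different things, and the prevalence
column must count sign *presence* at some observation inside the window —
consistent with signs persisting once appeared. The package defaults to the
presence reading (`method = "presence"`) and offers the first-onset reading
(`method = "onset"`) for comparison.

**Mortality after onset.** Among decedents ever exhibiting the sign, the
fraction whose death follows the first appearance within the horizon.
Horizon comparisons are inclusive (`≤`) everywhere: "within 72 hours" reads
naturally as ≤ 72 h, and the boundary convention is stated once and used by
every operation.

**Backward Kaplan–Meier onset.** Each exhibitor contributes an event at
`u = (death − onset)/24` days. The median is the smallest `u` with estimated
survival ≤ 0.5; the 95% CI is the Brookmeyer–Crowley construction: the
pointwise log(−log) confidence band (Greenwood variance, delta method) is
intersected with the 0.5 line. The estimator is implemented in the package
(`km_fit()`) rather than delegated, so the test suite can hold it against
`survival::survfit(conf.type = "log-log")` as a genuinely independent
reference; they agree to 1e−9 on censored data. By default the risk set is
exhibitors only — a "None" onset entry for a never-observed sign (apnea)
implies non-exhibitors were not pooled — but
`include_nonexhibitors = TRUE` enters them right-censored at their observed
span, since the source's exact censoring scheme is unstated.

## OR-rule models

For a subset S of the 12 predictors, the rule event is the *earliest* first
event among members; a decedent is a success when the rule fires and death
follows within the horizon. The prediction probability divides successes by
all decedents — patients with no member event, or an event too far from
death, are failures. Internally each decedent × predictor is reduced to a
lead time (death − first event, `−Inf` when absent); the rule's lead is the
row-wise maximum, so the exhaustive search over all C(12, m) subsets is a
sequence of vectorised maxima. The search is exhaustive by construction; a
regression test checks it against a naive enumerator written independently
in the test helpers.

Ties between equal-probability subsets are broken toward the
lexicographically smallest catalog index sequence (the catalog order is
fixed and documented); all tied optima remain retrievable. Note that the
best attainable probability is *not* monotone in m: adding a member can pull
the rule event earlier and push it outside the horizon. The test suite
asserts only that this may occur, not that it must.

**Cross-validation.** Patients are randomly partitioned (mandatory seed,
echoed in all outputs) into k = 10 folds differing in size by at most one.
Within each training split the best subset is *re-searched* and then scored
on the held-out fold; held-out successes are pooled over folds
(micro-average), with the fold-mean macro-average also reported. Per-fold
re-selection is the default because the published cross-validated accuracies
fall below training accuracies by up to ~15 points, which is the signature
of re-selection; re-scoring a fixed full-data subset is available via
`reselect = FALSE`. Pooling is the default aggregate because fold sizes are
unequal at n = 50, k = 10.

## The synthetic generator: what it emulates, and what it does not

The raw 50-patient data are not deposited, so the pipeline is exercised on
generated cohorts. The generator states a world matched to the published
marginal structure:

- observation spans lognormal with mean 14.1 and sd 15.6 days (the published
  observation-period moments), clipped below at 1 day and rounded to the
  12-h grid; death at the end of the span;
- per-sign occurrence probabilities equal to the published within-72-h
  prevalence fractions (apnea 0) and onset leads drawn, by default, from an
  exponential parameterised by the published median (rate `log(2)/m_s`) —
  right-skewed with occasional early onsets, matching the wide published
  CIs; a lognormal family is selectable; onsets are clipped into the
  observed span; signs persist once on;
- vitals as patient-level Gaussian baselines plus a linear terminal ramp
  over the final 72 h (SBP −35 mmHg, HR +22 bpm, and analogous drifts for
  DBP, temperature, respiratory rate, SpO2) plus observation noise. Baselines
  put the mean shock index near 0.8 and the ramp carries it above 1.0 in the
  final day or two, reproducing the qualitative published trajectory shape.
  These four headline numbers are the package's own choices of a realistic
  dying-phase drift; no published curve values were read off a figure.

Signs are correlated only through their shared anchoring to the death time —
there is no explicit sign–sign copula — and survivors (off by default) are
censored at span end without sign events. Consequently a green test
establishes that the *pipeline arithmetic* is right on data with the stated
marginals; it does not establish that real joint sign dynamics are captured,
and the generated cohorts are systematically "easier" for the OR-rule search
(independent high-prevalence signs inflate training probabilities relative
to the published 86%).

## Numerical and boundary choices

- Backward trajectory bin b covers `(12·b, 12·(b+1)]` hours before death;
  an observation at the death instant falls in bin 0.
- SI event uses strict `>` (the predictor is defined as SI > 1.0); the
  threshold-monotonicity property (raising the threshold never gives an
  earlier event) is property-tested.
- The meal discontinuation rule triggers at the end of the second
  consecutive qualifying day — the earliest instant at which the rule is
  decidable, since the source does not state the censoring instant.
- The published demographic table prints a male percentage inconsistent with
  its own count (16 of 50 shown as 22.9%); sex is carried but used in no
  computation. The published trajectory figure caption says "median ± sd"
  while the text says mean; the mean is the default with `stat = "median"`
  available.
- Percentages in exported CSVs are printed to one decimal next to
  full-precision machine-readable columns.

## Known limitations

- No interval-censored onset model; no imputation of missing vitals.
- No sign–sign dependence beyond death-time anchoring (v1 limitation).
- The published model-table accuracies cannot be recomputed without the
  undeposited raw data; the package reproduces the table *structure* and its
  arithmetic, and the acceptance suite targets only quantities that are
  exact functions of the published per-sign counts.
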