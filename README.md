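# sidmodels

Statistics and short-horizon prediction models for **signs of impending death
(SID)** in dying-phase cohorts.

In the last days of life, bedside physical signs — death rattle, respiration
with mandibular movement, peripheral cyanosis, pulselessness of the radial
artery, and others — appear in a fairly stereotyped order, and their onset
carries prognostic information that families and clinicians need for
end-of-life decisions. `sidmodels` implements the full analysis pipeline for a
longitudinal cohort observed roughly every 12 hours until death:

- **Cohort container + CSV I/O** for a per-patient table and a long
  observation table (11 charted sign flags with explicit missingness, plus
  vitals), with strict invariant checking and the study's
  observation-discontinuation rules.
- **Shock index** SI = HR / SBP, its first crossing of 1.0 as a derived 12th
  predictor, and binned backward-from-death vitals trajectories.
- **Per-sign statistics**: prevalence within 72 h of death, mortality within
  72 h / 24 h of first appearance, and the median onset *backward from death*
  by a hand-implemented Kaplan–Meier estimator with Brookmeyer–Crowley 95%
  confidence intervals.
- **OR-rule best-subset search**: for a subset S of the 12 predictors, the
  rule fires at the earliest member event; its prediction probability at
  horizon h is

      P_m(S; h) = #{ patients: some member event occurred and
                     death − earliest member event ≤ h } / #decedents

  maximised exhaustively over all C(12, m) subsets for each m = 1..12 and
  each horizon (7 days, 72 h, 24 h), with 10-fold cross-validation
  (the subset is re-searched inside every training split; held-out successes
  are pooled).
- **Synthetic cohort generator** calibrated to the published per-sign
  occurrence probabilities and onset medians, with vitals drifting so the
  shock index typically crosses 1.0 near death — the raw patient data are not
  deposited, so every stage is exercised on generated cohorts.

## Worked example

```r
library(sidmodels)

cfg <- generator_config(n_patients = 50, seed = 7)
x   <- generate_cohort(cfg)
x
#> <sid_cohort> 50 patients (50 died, 0 censored), 1872 observations

head(summarize_signs(x), 3)
#>                    sign km_median_days ci_low ci_high n_within72h prevalence_pct mort72_num mort72_den mort72_pct mort24_num mort24_den mort24_pct
#> 1 resp_verbal_decreased            1.5    0.5     2.0          40             80         31         40   77.50000         19         40      47.50
#> 2 resp_visual_decreased            2.0    0.5     2.5          35             70         23         35   65.71429         14         35      40.00
#> 3   peripheral_cyanosis            1.5    0.0     1.5          16             32         14         16   87.50000          7         16      43.75

L <- lead_matrix(x)
best_subset(L, 3, "7d")[c("subset", "prob_raw")]
#> $subset
#> [1] "resp_verbal_decreased" "peripheral_cyanosis"   "pulseless_radial"
#> $prob_raw
#> [1] 0.98

cv_probability(L, 3, "7d", seed = 7)$prob_10fcv
#> [1] 0.96
```

Each `summarize_signs()` row reads: 40/50 of this synthetic cohort showed a
decreased verbal response within 72 h of death (80%); of the 40 decedents
ever showing it, 77.5% died within 72 h and 47.5% within 24 h of its first
appearance; its median onset was 1.5 days before death (95% CI 0.5–2.0).
The best 3-predictor OR-rule predicts death within 7 days for 98% of this
cohort on training data and 96% under 10-fold cross-validation.

## Command line

```sh
Rscript inst/exec/sid generate --n 50 --seed 7 --out out/
Rscript inst/exec/sid report --patients out/patients.csv \
    --observations out/observations.csv --out out/report --seed 7
```

`report` writes `sign_summary.csv` plus one `model_table_<horizon>.csv` per
horizon and a JSON manifest echoing seed and versions; reruns are
byte-identical.

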