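# pvsignal

Disproportionality signal detection and time-to-onset modelling for
spontaneous adverse-event reports.

## What this package is for

Post-marketing drug safety relies on spontaneous reporting systems (SRS)
such as the FDA Adverse Event Reporting System (FAERS): voluntary case
reports with no at-risk denominator. The standard way to screen such data
is **disproportionality analysis** — for every (drug, event) pair, build the
2×2 table

|                 | event     | other events |
|-----------------|-----------|--------------|
| **target drug** | a         | b            |
| **other drugs** | c         | d            |

and ask whether `a` exceeds its independence expectation
`E = (a+b)(a+c)/N`. `pvsignal` implements the full workflow a
pharmacovigilance analyst runs on FAERS-style extracts:

* **Ingest**: read `"$"`-delimited quarterly tables (DEMO/DRUG/REAC/THER/
  OUTC), parse partial dates, deduplicate cases by the FDA rule (latest
  FDA_DT per CASEID, ties to the largest PRIMARYID), link to case-level
  reports, and extract the primary-suspect cohort for a named drug.
* **Describe**: baseline tables (sex, age group, year, region, reporter,
  seriousness) with printed-convention rounding, for case-level cohorts and
  for aggregate-only count tables.
* **Detect signals**: four estimators per event at MedDRA PT and SOC level —
  reporting odds ratio (ROR) with Wald CI, proportional reporting ratio
  (PRR) with Yates-corrected χ², the Bayesian confidence propagation (BCPNN)
  information component `IC = log₂[p(drug,event)/(p(drug)p(event))]` with
  exact posterior moments, and the empirical-Bayes gamma-Poisson shrinker
  (MGPS) `EBGM = 2^{E[log₂λ]}` with a fitted two-component gamma mixture
  prior — combined into the six-condition signal rule
  `a ≥ 3 ∧ PRR ≥ 2 ∧ χ² ≥ 4 ∧ ROR₀₂.₅ > 1 ∧ IC025 > 0 ∧ EBGM05 > 2`.
* **Model onset**: time to onset in days (event date − therapy start),
  30-day monthly histograms, maximum-likelihood Weibull fit with
  failure-type classification (shape < 1 ⇒ early failure), the median with
  its normal-approximation CI, cumulative incidence, and a sex-stratified
  Wilcoxon rank-sum comparison.
* **Simulate**: a synthetic-report generator with planted relative-risk
  structure, injected duplicates, configurable missingness and
  Weibull-distributed onsets, so every stage above is testable against
  known ground truth without downloading anything.

Everything is data-frame-in / tibble-out and pipe-friendly, with
`tidy()`/`glance()` methods for fitted objects and `autoplot()`/`plot_*()`
functions for the result types.

## Worked example

```r
library(pvsignal)

cfg <- synthetic_config(n_reports = 5000, seed = 2024)
report <- run_pipeline(run_config(synthetic = cfg))
report
#> <pv_run_report>
#>   stage                    n
#> 1 demo_rows_read        5250
#> 2 after_deduplication   5000
#> 3 linked_with_reaction  5000
#> 4 target_cohort          493
#> 5 tto_evaluable          356
#> flagged signals: 3 PT | 0 SOC
#> Weibull shape 0.668 -> early failure type
```

The funnel reads: 5,250 raw DEMO rows (5,000 cases plus 5% injected
duplicates) collapse to 5,000 after deduplication; 493 reports name the
target drug as primary suspect; 356 of those have both dates needed for
onset analysis.

```r
rank_signals(report$signals_pt, by = "ror", k = 5)[,
  c("event", "a", "ror", "ror_low", "prr", "chi2", "ic025", "ebgm05", "signal")]
#>                                    event   a  ror ror_low  prr   chi2   ic025 ebgm05 signal
#> 1                                MYALGIA 143 8.99   7.058 6.67 423.59  1.7497  3.599   TRUE
#> 2 BLOOD CREATINE PHOSPHOKINASE INCREASED 105 5.17   4.014 4.29 190.09  1.3144  2.802   TRUE
#> 3                                   GOUT  64 3.26   2.420 2.97  64.87  0.8519  2.232   TRUE
#> 4               BLOOD CREATINE INCREASED  31 1.71   1.154 1.67   6.65  0.0304  0.956  FALSE
#> 5                                PYREXIA  25 1.40   0.908 1.38   1.97 -0.2590  0.952  FALSE
```

Exactly the three planted associations (relative risks 8, 5, 3) pass all six
conditions; the strongest background event fails on `IC025` and `EBGM05`
despite a nominally elevated ROR — the conjunction rule doing its job.

```r
report$tto$fit
#> Weibull onset fit (n = 356)
#>   shape 0.668 (95% CI 0.614-0.722) -> early failure type
#>   scale 54.5 days (95% CI 45.5-63.4)
#>   parametric median 31.4 days; sample median 32.0 (95% CI 25.3 to 38.7)
```

The fitted shape recovers the generating value 0.68 within its interval:
a decreasing hazard, i.e. most events occur shortly after treatment start.

```r
report$sex_comparison
#>   stratum   n median    q1   q3 wilcoxon_p
#> 1  female 162     18  4.25 71.8    0.00667
#> 2    male 155     51 11.50 96.5    0.00667
```

A caution built into the example: the generator plants **no** sex
difference in onset, yet this seed produces p = 0.0067 — a reminder that a
single unadjusted stratified comparison can look convincing by chance.

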