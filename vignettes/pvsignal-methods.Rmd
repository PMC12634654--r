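---
title: "Methods: disproportionality signals and time-to-onset in spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signals and time-to-onset in spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem

Spontaneous reporting systems (SRS) such as the FDA's FAERS collect
voluntarily submitted adverse-event reports. They have no at-risk
denominator, so absolute incidence cannot be estimated; instead,
*disproportionality analysis* asks whether a (drug, event) pair is reported
more often than expected if drug and event were independent within the
database. `pvsignal` implements the full desk workflow for this kind of
study: ingesting FAERS-dialect quarterly files, deduplicating cases the way
the FDA recommends, building 2×2 contingency tables per event at the MedDRA
preferred-term (PT) and system-organ-class (SOC) levels, computing four
disproportionality estimators combined into a strict signal rule, and
modelling time to onset (TTO) with a Weibull distribution.

Because the real databases are large, access-restricted (VigiAccess exposes
only aggregate distributions; MedDRA is licensed), and ever-changing, the
package also ships a synthetic-report generator with known ground truth.
Every pipeline stage is validated against that ground truth rather than
against any specific database extract.

## Case ingestion and deduplication

Quarterly files are `"$"`-delimited ASCII with an uppercase header (DEMO,
DRUG, REAC, THER, OUTC). Dates carry 8, 6 or 4 digits; 6-digit dates are
imputed to the first of the month (tolerable given monthly onset binning,
below), while 4-digit dates can support annual tabulation but not onset
computation. Duplicates are resolved per CASEID: the report with the most
recent FDA receipt date survives, ties broken by the largest PRIMARYID. The
operation is idempotent and its survivors are checked exactly against the
generator's manifest in the test suite.

Reports qualify for the analysis cohort when a drug row matches the target
name — after trimming, whitespace-collapsing and upper-casing, against a
user-extendable synonym list — with the primary-suspect role code (`"PS"` by
default, configurable). Name matching is exact-after-normalization rather
than fuzzy: auditable, and the right default for a single well-defined
generic name. A report is *serious* exactly when it has at least one outcome
row, so seriousness is a patient-level, not event-level, attribute.

## The four estimators

All are computed from the per-event 2×2 table
(a, b, c, d) with `N = a+b+c+d` and expected count `E = (a+b)(a+c)/N`:

* **ROR** `= ad/bc`, Wald 95% CI `exp(log ROR ± 1.96·√(1/a+1/b+1/c+1/d))`.
  Undefined with a zero cell; an optional Haldane 0.5 correction (off by
  default) is available. Leaving it off is safe because the signal rule
  already requires `a ≥ 3`.
* **PRR** `= [a/(a+b)]/[c/(c+d)]` with the Yates-corrected χ²
  `N(|ad−bc|−N/2)²/[(a+b)(c+d)(a+c)(b+d)]`, floored at zero. Yates
  correction is the common convention behind the `χ² ≥ 4` threshold and can
  be disabled.
* **BCPNN information component** `IC = log2[p(drug,event)/(p(drug)p(event))]`
  under independent beta priors with hyperparameters `α₁ = β₁ = 1`,
  `α = β = 2` and the joint-cell prior weight chosen so the *prior* IC
  expectation is zero. The posterior mean and variance of each `log p` term
  are digamma/trigamma functions of the updated beta parameters, so the
  posterior moments are exact, and `IC025 = E(IC) − 2·sd(IC)`. A consequence
  worth knowing: the exact posterior mean of a log-ratio is slightly
  negative at small counts even when `a = E` (Jensen's inequality); by
  `a ≥ 10` the bias is within ±0.1 bit. A simpler shrinkage variant
  `IC = log2[(a+0.5)/(E+0.5)]` is available as a configuration choice.
  The closed form is verified against a 10⁵-draw Monte-Carlo posterior in
  the tests.
* **MGPS / EBGM**: counts follow `a ~ Poisson(λE)` with the reporting-rate
  multiplier `λ` drawn from a two-component gamma mixture. The mixture is
  fitted empirically by maximizing the summed negative-binomial marginal
  likelihood (L-BFGS-B on log/logit-transformed parameters from the
  conventional start `(0.2, 0.1, 2, 4, 1/3)`; box constraints `e⁻⁷–e⁷` keep
  components away from degenerate point-mass spikes that the unbounded
  likelihood admits). The posterior is a reweighted gamma mixture;
  `EBGM = 2^{E[log₂ λ]}` has a closed form in digamma functions and `EBGM05`
  is found by root-finding on the mixture CDF to 10⁻⁶ relative tolerance.
  Both are verified to 1% against direct numerical integration on a 50-table
  grid, and against the conjugate closed form when the mixture collapses to
  one component. In the pipeline the prior is fitted once on the PT-level
  tables and reused at SOC level, where there are too few rows for a stable
  five-parameter fit.

A pair is a **signal** iff all six hold: `a ≥ 3`, `PRR ≥ 2`, `χ² ≥ 4`, lower
95% ROR bound `> 1`, `IC025 > 0`, `EBGM05 > 2`. The conjunction is the
false-positive control — no multiplicity correction is applied, matching
field practice. Every threshold is a configuration value.

At SOC level a report contributes at most once per SOC regardless of how
many of its PTs map there (report-level 2×2 semantics); event-level counting
is available behind a flag since conventions differ between groups.

## Time to onset

TTO is the whole-day difference between the event date (DEMO) and the
earliest parseable therapy start date for the target drug (THER). Missing
or negative intervals are excluded and counted; zero is a legitimate onset
day and is retained. Monthly histograms use 30-day half-open bins
(`[30(m−1), 30m)`), the common TTO convention.

The Weibull fit maximizes the likelihood via the profile equation: for fixed
shape the MLE scale is closed-form, and Newton iteration solves the profile
score in the shape (converging in a handful of steps; a damped step keeps
the shape positive). Zero days are shifted to 0.5 for the likelihood only,
because the Weibull log-density is undefined at zero; medians and IQRs keep
the raw zeros. Confidence intervals are `estimate ± 1.96·SE` on the natural
scale from the inverse observed information — the natural (not log) scale is
used because published shape intervals in this literature are symmetric
about the estimate. Shape `< 1` classifies the hazard as *early failure*
(decreasing hazard: events cluster shortly after initiation), `> 1` as
*wear-out*, with a ±0.05 band around 1 called *random*.

The median's CI uses the normal approximation
`median ± 1.96/(2·f̂(median)·√n)` with a Gaussian-kernel density estimate
`f̂`; the lower bound is deliberately reported unclipped, so it can be
negative for right-skewed samples — an artefact of the approximation that
the output annotates, since true onset times are non-negative. The
sex-stratified comparison is a two-sided Wilcoxon rank-sum test with tie
correction under the normal approximation (a plain rank-sum test, not a
survival-weighted variant: TTO samples here are complete, with no censoring
model — an SRS has no at-risk population to censor from).

## The synthetic generator

`synthetic_config()` describes the simulated snapshot; its defaults are the
package's reference study conditions:

* 2,000 reports, one target drug assigned as primary suspect with
  probability 0.10, 20 background drugs, and about a third of reports
  carrying an additional concomitant drug row (which may name the target —
  exercising the role-code filter).
* Events are independent Bernoulli per PT at background probability 0.04
  over a vocabulary drawn from the bundled dictionary stub; three planted
  pairs at relative risks 8, 5 and 3 emulate the strong/moderate/weak mix a
  real screen returns. A report with no drawn event receives one
  drug-independent uniform PT so every case has a reaction without
  distorting 2×2 association structure.
* Onset is `Weibull(shape 0.68, scale 45 days)` added to therapy start —
  an early-failure profile with a scale in the first-quarter range typical
  of published TTO analyses; dates span 2004–2024.
* Missingness: 20% age, 10% sex, 30% therapy dates; 5% duplicates injected
  as later re-reports with larger PRIMARYIDs (so the expected dedup
  survivor is recorded in the manifest); 17% serious, matching the ~83%
  non-serious fraction typical of consumer-heavy databases.

What the generator does *not* emulate: drug-name misspellings, report-level
event correlation (events are conditionally independent given the drug),
multi-drug interaction structure, secular reporting trends, and the
legacy pre-2012 file schema. Passing tests therefore demonstrate
correctness of the statistical machinery under a clean generating model,
not robustness to the full messiness of real extracts.

## Validation problem sizes

The test suite validates at sizes chosen to make sampling error negligible
relative to each tolerance: estimator formulas on exact hand-enumerable
tables; EBGM against quadrature on 50 tables; Weibull shape recovery at
n = 2,000 across 20 seeds for shapes 0.5–1.5 (mean within 2%, interval
coverage ≥ 18/20) and n = 5,000 at shape 0.68 (±0.04); planted-signal
detection at relative risk 10 with 50,000-report bundles across 20 seeds
(≥ 19/20 flagged); null calibration with 20,000-report bundles across 20
seeds (< 5% of pairs with `a ≥ 3` flagged).

## Known limitations

* Disproportionality quantifies reporting association, not causation or
  incidence; the package deliberately reports nothing it cannot compute
  from the 2×2 tables.
* The aggregate-table path (VigiAccess-style) supports descriptive tables
  only; building comparator cells (c, d) from an aggregate-only interface
  requires externally supplied database totals.
* The bundled PT→SOC stub covers ~65 common terms for demonstration and
  testing; real analyses should supply a licensed MedDRA export in the same
  CSV layout.
* Stratified or regression-adjusted disproportionality and
  censoring-aware onset models are out of scope.
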