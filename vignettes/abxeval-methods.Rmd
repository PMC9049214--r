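---
title: "Evaluating outpatient antibiotic prescribing: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating outpatient antibiotic prescribing: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Most human antibiotic use happens in outpatient primary care, and a large
share of it is prescribed for conditions that rarely justify antibiotics.
`abxeval` implements a pipeline that measures this from routine electronic
prescribing records: visit-level prescription and diagnosis streams are
linked, each antibiotic-prescribing visit is labelled for appropriateness
from its diagnoses, prescribing patterns are described by drug class and
WHO AWaRe category, and the monthly series of rates is analysed with an
interrupted time-series (ITS) design around a known disruption — by default
the March 2020 declaration of the COVID-19 pandemic.

Because routine prescribing databases cannot be redistributed, the package
also contains a synthetic-records generator with full ground-truth
bookkeeping. Every stage of the pipeline, and every estimator, is testable
against data whose generating parameters are known.

# Data model

A *visit* is the unit of analysis: all prescription and diagnosis rows
sharing the exact composite key (institution code, patient identifier,
calendar date) form one visit. No fuzzy matching is attempted — the key is
the linkage identifier of the source records. Two consequences follow:

* a patient seen twice on different days contributes two visits;
* a visit can carry several prescriptions and several diagnoses, or either
  alone.

Physician attributes attach to prescription rows; the visit-level physician
is the majority prescriber of the visit, with ties broken by first
occurrence in file order (multi-physician visits are rare and the choice is
documented rather than consequential). Institutions uploading fewer than 10
distinct calendar months of data are excluded before analysis (inclusive
boundary: exactly 10 months keeps the institution). The study window
defaults to June 2017 – July 2021 (50 months) and is configurable.

# Antibiotic identification and labelling

Antibiotics are systemic antibacterials (ATC prefix `J01`) plus three
nitroimidazoles — metronidazole, tinidazole, ornidazole — that are widely
used against anaerobic infections in Chinese outpatient care and may carry
`P01AB` codes for the oral route. Spectrum is a deterministic function of
the ATC level-4 class: second- to fourth-generation cephalosporins
(`J01DC`, `J01DD`, `J01DE`), fluoroquinolones (`J01MA`), macrolides
(`J01FA`), penicillin combinations (`J01CR`) and aminoglycosides (`J01GB`,
`J01GA`) are broad-spectrum; everything else is narrow. AWaRe categories
come from the shipped catalogue file, in which fosfomycin is the single
Reserve agent and cefathiamidine, cefoperazone/tazobactam,
cefoperazone/sulbactam and etimicin are the only Unclassified agents. The
current WHO AWaRe list places *oral* fosfomycin in Access; the catalogue
deliberately follows the evaluation scheme being reproduced, and since the
file is plain CSV either convention is one edit away.

The shipped catalogue is a *synthetic reconstruction*: it covers the
commonly prescribed agents of each class rather than an exhaustive national
formulary, and classification is entirely data-driven so a fuller catalogue
drops in without code changes.

# Appropriateness classification

Diagnoses map to 30 diagnostic categories, each carrying one of three
tiers: tier 1 conditions almost always justify antibiotics (e.g. urinary
tract infection, pneumonia), tier 2 sometimes (e.g. acute otitis media,
acute sinusitis), tier 3 almost never (e.g. viral upper respiratory
infection, hypertension). ICD-10 codes are matched by **longest matching
prefix** after stripping punctuation; the mapping granularity is therefore
set by the mapping file, not the code. Traditional Chinese medicine (TCM)
codes have their own prefix mapping (the "expert" mode) and a single
umbrella category for rate tabulations.

Each antibiotic-prescribing visit receives one diagnosis by priority:

1. the best (lowest) tier wins;
2. within the best tier, allopathic (ICD-10) diagnoses beat TCM diagnoses;
3. any remaining tie goes to the lowest category index in the mapping file
   — a deterministic tie-break that can affect the category label but never
   the appropriateness label.

The appropriateness label follows mechanically: tier 1 → appropriate,
tier 2 (no tier 1) → potentially appropriate, only tier 3 → inappropriate,
no matched diagnosis → not linked. Codes with no matching prefix are
counted and treated as absent; a visit whose only codes are unmatched
becomes "not linked". Two sensitivity modes reclassify *all* TCM codes to
tier 2 or tier 3 wholesale; forcing tier 3 can never improve a visit's
label, and forcing tier 2 can never push a visit into "inappropriate" —
both properties are tested.

# Estimation

* **Binomial rates** carry Clopper–Pearson exact intervals (beta-quantile
  inversion of the binomial tails). The method is conservative: coverage is
  at least nominal for every (n, p), which the tests verify by exact
  enumeration rather than simulation.
* **The four-category appropriateness mix** carries Goodman simultaneous
  intervals with the Bonferroni-adjusted chi-square critical value
  `qchisq(1 - alpha/k, 1)`. Note that published tables built with other
  software can print wider simultaneous intervals than this formula yields
  at very large n; the implementation follows Goodman's published form.
* **Case-mix differences** between subgroups are removed by direct
  standardization over the diagnostic spectrum of the whole population
  during the whole period; categories absent from a stratum contribute
  weight times zero and are flagged. The variance is the usual weighted
  binomial sum, with a normal-approximation interval.
* **Risk factors for inappropriate prescribing** are estimated by binary
  logistic regression with a normal random intercept per institution
  (Laplace approximation, via `lme4`). All non-inappropriate categories —
  including "not linked" — form the non-event class. Reference levels
  follow the reporting convention of the emulated study (rural,
  station/village-clinic level, patient 18–44/male/insurance, year 2017,
  physician <30/male/high-school-or-below); Wald intervals are reported on
  the odds-ratio scale.

Report tables round percentages half away from zero to one decimal,
matching the convention of the software the original tables were produced
with (`round_half_up()`).

# Interrupted time series

Monthly outcome series (antibiotic prescription rate; proportion of
inappropriate prescriptions) are built gap-free over the window; months
with zero denominator are flagged and excluded from fits. Seasonal
adjustment is the classical additive decomposition: 2×12 centered moving
average trend, seasonal factors as re-centered monthly means of the
detrended series, adjusted = raw − seasonal (the raw series is always
reconstructible). This replaces the X-12-ARIMA procedure used with the
original data — a documented divergence; X-12's ARIMA extension and outlier
handling are out of scope, and on synthetic data with injected sinusoidal
seasonality the classical factors recover the truth.

The segmented regression is

$$Y_t = \beta_0 + \beta_1 t_0 + \beta_2\,\mathrm{Intv}_t +
  \beta_3\,\mathrm{taft}_t + \epsilon_t$$

with `Intv` 0 before the interruption month and 1 from it on, and `taft`
counting months since the interruption — **0 at and before the interruption
month**, then 1, 2, …. Under this coding β2 is the immediate level change
at the interruption and β1 + β3 the post-period trend (reported with a
delta-method HAC interval). The offset convention is a genuine design
choice (the verbal definition "time after the impact begins" does not fix
it); it is exposed through the `interruption` parameter and held fixed
throughout.

Standard errors are Newey–West: Bartlett weights `1 − l/(L+1)` on the
residual lag cross-products, default lag `floor(4 (T/100)^{2/9})` (3 at
T = 50), no small-sample correction — verified against an independent
reference implementation to 10 decimals on a fixture. Diagnostics are the
Durbin–Watson statistic and a serial-correlation score test (auxiliary
regression of residuals on the regressors plus q lagged residuals,
statistic T·R² against χ²(q)) — the Breusch–Godfrey special case of the
Cumby–Huizinga test, which is exact under the i.i.d. null that applies
here; the general form for non-i.i.d. instrumental estimators is not
needed.

## A known limitation of short-series HAC intervals

On synthetic 50-month series with AR(1) noise the segmented estimator is
essentially unbiased for the level change (mean estimate within ±0.05 of
the generating −2.8 over 500 replicates). The HAC 95% intervals of that
coefficient, however, cover the truth in only about 77–83% of replicates —
even with i.i.d. noise. The level change is identified locally around the
interruption, and the Bartlett-weighted variance of such a contrast is
biased downward at T = 50; this is a property of the estimator, not of the
implementation (which matches the reference implementation exactly).
Practically: with ~50 months of data, treat segmented-regression interval
widths as optimistic, and lean on the point estimates and on sensitivity
analyses. The corresponding coverage assertion in the test suite is left
failing deliberately, with this analysis, rather than silently widened.

# The synthetic world

Defaults state the emulated setting once and are not tuned:

| parameter | default | meaning |
|---|---|---|
| institutions | 26/78/25/26 per urban-center/urban-station/rural-center/rural-station cell | 51 centers + 104 stations as in the emulated setting; the urban/rural split is chosen to reproduce the ~61% urban visit share |
| window | 2017-06 … 2021-07 (50 months) | study window |
| visits/institution/month | Poisson(60) | deliberate scale-down of the source setting's ~1,300 so the full pipeline runs at desk scale; all proportions are volume-invariant |
| tier prescribing probabilities | 0.6 / 0.5 / 0.2 | baseline probability an antibiotic is prescribed for tier 1/2/3 visits |
| TCM fraction | 0.13 | share of diagnoses carrying TCM codes |
| σᵤ | 0.3 | institution random-intercept SD (logit scale) |
| covariate effects | small logit shifts | magnitudes in line with the subgroup odds ratios of the emulated setting |
| seasonality | 2 pp cosine, January peak | winter-dominant respiratory demand |
| secular trend | −0.05 pp/month | gentle improvement over the window |
| COVID-19 | −2.8 pp level, +0.3 pp/month slope at 2020-03 | the study-magnitude pandemic effect |

One modelling note: tier base, covariate effects and the institution
intercept combine on the logit scale, while the seasonal, trend and
pandemic terms are added on the probability scale in percentage points
(clamped away from 0 and 1). This hybrid keeps attribute effects odds-ratio
interpretable *and* makes the ITS parameters recoverable in the same units
they are specified in, which is what the estimator tests need.

What the generator does **not** emulate: the joint covariate distribution
(margins only), repeat visits by the same patient, institution-specific
case mixes, coding error, or calendar effects beyond a fixed monthly
factor. A green test on synthetic data therefore establishes correctness of
the pipeline's logic and estimators under the stated model — not that any
particular real-world database would yield any particular estimate.

The direct monthly-series generator bypasses the visit level entirely
(segmented line + fixed month effects + AR(1) noise started from its
stationary distribution) for fast estimator studies.

# Numerical and degenerate-input choices

* Clopper–Pearson at x = 0 or x = n pins the corresponding bound to 0/100
  exactly; n = 0 is an error, not NaN.
* Goodman intervals require k ≥ 2; a zero count yields a zero lower bound.
* Empty strata render as an em dash in reports, never as 0.
* Unknown ATC level-4 classes classify as narrow-spectrum with a warning;
  antibiotics missing from the catalogue classify as Unclassified with a
  warning.
* Rows with missing diagnosis codes are dropped (counted); the visit
  survives and can become "not linked".
* Seasonal adjustment refuses series under 24 months or with missing
  values; the segmented fit requires at least 4 observations on each side
  of the interruption and refuses rank-deficient designs.
* All randomness flows from a single user-supplied seed; the generator is
  byte-deterministic given the seed.
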