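# abxeval

Appropriateness evaluation of outpatient antibiotic prescribing from
visit-level electronic prescription records, with an interrupted
time-series analysis of a known disruption (by default the COVID-19
pandemic, March 2020).

The package is for pharmacoepidemiologists and health-services researchers
who have (or want to prototype against) routine primary-care prescribing
data: prescription and diagnosis event streams keyed by institution,
patient and date, plus attribute lookup tables.

## What it computes

**Appropriateness.** Diagnoses are mapped to 30 diagnostic categories in
three tiers (tier 1 almost always justifies antibiotics, tier 2 sometimes,
tier 3 almost never; traditional Chinese medicine codes carry their own
mapping and sensitivity modes). Each antibiotic-prescribing visit gets one
label by priority — best tier wins, allopathic beats TCM within a tier:

- *appropriate* (a tier-1 diagnosis), *potentially appropriate* (tier 2,
  no tier 1), *inappropriate* (only tier 3), *not linked* (no matched
  diagnosis).

**Patterns.** Antibiotics are identified as ATC `J01` plus the three
nitroimidazoles, and labelled with ATC level-4 class, broad/narrow
spectrum, and WHO AWaRe category (Access/Watch/Reserve/Unclassified).

**Estimation.** Clopper–Pearson exact intervals for rates,

    L = qbeta(alpha/2, x, n - x + 1),  U = qbeta(1 - alpha/2, x + 1, n - x),

Goodman simultaneous intervals for the four-category mix, direct
standardization over the whole-population diagnostic spectrum, and
random-intercept logistic regression (institution-level intercept) for
inappropriate prescribing.

**Interrupted time series.** Monthly series of the prescription rate and
of the inappropriate proportion, classical additive seasonal adjustment,
then segmented OLS

    Y_t = b0 + b1*t0 + b2*Intv_t + b3*taft_t + e_t

with Newey–West (Bartlett-kernel) standard errors, Durbin–Watson and
Breusch–Godfrey/Cumby–Huizinga autocorrelation diagnostics. `b2` is the
immediate level change at the interruption month; `b1 + b3` the post-period
trend.

**Synthetic data.** `simulate_dataset()` generates a full synthetic
prescribing database (institutions, physicians, patients, diagnoses,
prescriptions) with known tier-wise prescribing probabilities, covariate
effects, institution random intercepts, seasonality and a pandemic
step/slope — plus ground-truth bookkeeping, so the entire pipeline runs
and is testable with no access to any real database.

## Worked example

```r
library(abxeval)

cfg <- simulation_config(seed = 2024,
  n_institutions = c(urban_CHSC_TH = 5, urban_CHSS_VC = 8,
                     rural_CHSC_TH = 5, rural_CHSS_VC = 8),
  mean_monthly_visits = 40)
sim <- simulate_dataset(cfg)
d <- file.path(tempdir(), "sim"); o <- file.path(tempdir(), "out")
write_dataset(sim, d)

bundle <- run_pipeline(list(
  prescriptions = file.path(d, "prescriptions.csv"),
  diagnoses    = file.path(d, "diagnoses.csv"),
  patients     = file.path(d, "patients.csv"),
  physicians   = file.path(d, "physicians.csv"),
  institutions = file.path(d, "institutions.csv"),
  out_dir = o, seed = 1))
cat(render_summary(bundle))
```

```
# Antibiotic prescribing evaluation summary

- Overall antibiotic prescription rate: 16.2% (8348/51628)
- Appropriate: 10.8% (900/8348)
- Potentially appropriate: 35.4% (2952/8348)
- Inappropriate: 53.9% (4496/8348)
- Not linked to any diagnosis: 0.0% (0/8348)
- Broad-spectrum share of items: 63.1%
- Watch share of items: 59.9%

## Interrupted time series
- Prescription rate: trend before -0.1 (-0.1 to -0.0); level change -1.8
  (-2.6 to -1.0); slope change 0.3 (0.2 to 0.4); trend after 0.2 (0.2 to 0.3)
- Inappropriate proportion: trend before -0.1 (-0.2 to 0.0); level change
  -5.7 (-8.3 to -3.2); slope change 0.6 (0.5 to 0.8); trend after 0.6
  (0.4 to 0.7)
```

Reading it: 16.2% of the 51,628 synthetic visits ended with an antibiotic;
53.9% of those were for tier-3 (almost-never) diagnoses; the pipeline
estimates an immediate drop in the prescription rate at March 2020 followed
by a rising monthly trend — the shape injected by the generator. (At this
deliberately small volume the per-month sampling noise is large, so point
estimates sit within a band around the generating values; the estimator
itself is exercised at scale in the test suite.)

Exact rate intervals work standalone:

```r
clopper_pearson_ci(32, 323)
#>       x     n  rate ci_low ci_high alpha method
#> 1    32   323  9.91   6.88    13.7  0.05 clopper_pearson
```

The bundle written to `out_dir` contains `table1_characteristics.csv`,
`fig1_rates_by_category.csv`, `table2_appropriateness.csv`,
`pattern_aware_spectrum.csv`, `its_results.csv` and a `run_log.txt` with
seed, row counts and all configuration switches.

## Acceptance script

`scripts/acceptance.R` recomputes, from scratch with the installed package:
the upper Clopper–Pearson 95% bounds for two published numerator/denominator
pairs (32/323 and 1,981/11,216), and the mean estimated level-change
coefficient of the segmented regression across 500 synthetic 50-month
series generated with a known −2.8 level change and AR(1) noise. Run it
from the repository root:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Notes

- The shipped tier map and antibiotic catalogue are synthetic
  reconstructions (plain CSV, fully editable); classification is
  data-driven.
- The methods vignette (`vignettes/abxeval-methods.Rmd`) documents the
  models, the priority and tie-break rules, the seasonal-adjustment
  stand-in, the synthetic world's defaults, and a known undercoverage
  limitation of short-series Newey–West intervals.
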