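---
title: "Methods: matched-cohort cost-of-illness estimation from register data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: matched-cohort cost-of-illness estimation from register data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regcost)
```

## The design

`regcost` estimates the economic burden associated with mental disorders
from person-level register tables, using a prevalence-based matched
case-cohort design. The estimand is descriptive, not causal: for each
disorder it answers "how do the observed costs of diagnosed persons differ
from those of comparable undiagnosed persons?".

Three ingredients define the design:

* **Censored follow-up.** Every person contributes the half-open interval
  `[max(2004-01-01, birth, immigration), min(death, 95th birthday,
  emigration, 2017-04-23))`. All intervals in the package are half-open;
  a person who dies on a given date contributes no person-time on that
  date, and eligibility "alive at the index date" means death strictly
  after it. Person-time within a calendar year is the day-count overlap
  divided by the year length (366 in leap years).

* **Case definition.** A case of disorder *d* is a person with at least one
  psychiatric hospital contact (inpatient, outpatient or emergency) whose
  ICD-10 code starts with one of *d*'s code prefixes, dated 1995–2017, at
  an age at or above the disorder's assumed earliest onset age. The index
  date is the earliest such event. A person can be a case for several
  disorders; the "any mental disorder" aggregate uses the union of the 18
  code sets. Prefix matching is deliberate: sub-coded dialect variants
  ("F32.11") must match "F32".

* **Incidence-density matching.** Each case receives up to 10 controls
  drawn uniformly at random (seeded) from candidates of the same sex whose
  birthdate lies within ±2 calendar months — calendar arithmetic with
  clamping to month ends, not a fixed day count — and who are alive,
  resident and free of the index disorder on the index date. Eligibility is
  assessed **only at the index date**: a control later diagnosed with the
  index disorder remains a control for that set (the quoted design wording
  supports this reading; `study_config(control_history = "ever")` offers
  the stricter alternative without presuming intent). Controls may be
  reused across sets — unavoidable in a finite population with a 1:10
  ratio — but never within a set. Sets that cannot be filled are kept,
  flagged as deficient, and logged.

## Cost panels

Annual register amounts are nominal local currency. Each component is
summed per person-year, inflation-adjusted with a GDP-deflator ratio
`deflator(2017)/deflator(year)` and converted to Euro at the 2017 average
exchange rate. Subsidised prescription cost is service cost minus the
out-of-pocket patient cost; negative differences (possible only under
noisy synthetic inputs) are floored at zero with a warning. Combined
healthcare cost is the sum of psychiatric DRG, somatic DRG, subsidised
prescription and primary-care cost; out-of-pocket cost is carried as its
own column and excluded from the combination. Income and the nine transfer
components are deflated with the same index — whether productivity losses
should use a wage index instead is a judgement call; one price index for
all money fields keeps components commensurable.

## Estimation

Within a matched set and calendar year the excess for component *c* is

$$ D = C_{\text{case}} - py_{\text{case}} \cdot
   \frac{\sum_i C_{\text{ctl},i}}{\sum_i py_{\text{ctl},i}} $$

Scaling the control *rate* by the case's full-year person-time makes the
null exact under censoring: if cases and controls share a cost process,
$E[D] = 0$ whatever the pattern of deaths and emigrations, because annual
cost lumps are proportional to exposure in expectation. Set-years whose
controls have no person-time are skipped and counted in diagnostics rather
than imputed.

The three measures are: nationwide annual (sum of $D$, or of case costs for
absolute measures, divided by the 13.31-year window length — a person-year
weighted "average year", the coherent reading of a 14-calendar-year window
whose last year is partial); per-case annual (total divided by case
person-years counted **from the index date**, so the index-year panel lump
is matched against a part-year denominator, which the null-exact form of
$D$ compensates on the control side); and per-capita (nationwide divided by
the stratum's population count on 2017-01-01). Per-person weighting for
per-case averages is available via `study_config(per_case_weighting =
"persons")`; person-years is the default because it handles censoring and
the partial final year without ad-hoc corrections.

Stratification: sex is the case's sex; age is the age attained on 1 July of
each calendar year, in 5-year bands 0–4 … 90–94. Both stratifiers partition
set-year contributions, so stratum values sum *exactly* to the overall
value — a conservation law the test suite asserts to 1e-9.

**Years since diagnosis.** Offsets are whole calendar years,
`year − year(index)`, with person-time from the index date; a case
diagnosed mid-2016 contributes offset 0 in 2016 and a fractional offset 1
in early 2017. Anniversary-based intervals may look more natural, but with
annual register lumps the within-year timing of a cost is unobservable, and
uniform apportioning across anniversary intervals provably distorts the
offset-0 to offset-1 ratio; calendar-year offsets keep the estimator an
unbiased reader of the generative decay. Only cases identified 2004–2017
enter this analysis, since costs are unobservable before 2004.

**Uncertainty.** `mc_se` is a between-set sampling standard error: sets are
treated as independent units, the per-case estimator as a ratio of set
totals (ratio-estimator variance), the nationwide estimator as a sum. No
confidence intervals are reported beyond this; the design is descriptive.

## The synthetic register generator

`simulate_registers()` emulates the six register tables at yearly
resolution with event dates uniform within the eligible part of the year.
Its defaults are the package's study conditions, chosen once:

* Population: births uniform 1955–2000, equal sexes, 5% immigrants, 0.2%
  annual adult emigration, Gompertz mortality `5e-5 · exp(0.085 · age)`.
* First-diagnosis hazards graded over 2e-5 to 1.5e-3 per year (common mood
  and anxiety disorders at the top, cocaine-use and conduct disorders
  rare), mirroring the relative frequencies of hospital-treated disorders
  in a Scandinavian-style population. Disorders arise independently of one
  another, so a case's other diagnoses cancel in expectation between the
  case and control arms.
* Baseline costs: lognormal draws with many exact zeros (e.g. somatic care
  used by ~55% of person-years, psychiatric care by 0.6% of non-cases),
  scaled by within-year exposure; income has an age hump over working ages;
  transfers follow age-dependent eligibility. All magnitudes are stated in
  2017 Euro and converted to nominal currency per register year, which is
  exactly what the costing module undoes.
* Disorder effects: per case-year excess psychiatric cost (default 2,500
  EUR), excess somatic cost (600 EUR), income decrement (8,000 EUR, floored
  so income stays non-negative; the realised amount is recorded) and
  transfer increment (4,000 EUR, booked as disability pension), each
  multiplied by `decay^k` in the k-th calendar year after diagnosis
  (default 0.85) and by the case's exposure.
* Register-extract horizon: cost, income and diagnosis rows end at the
  2017-04-23 data cut, as a real extract would; this also makes generated
  exposure and study person-time coincide, so enumerated expectations are
  exact.

Generation is fully vectorised under one seeded stream in a canonical
internal order, which makes bundles byte-identical under a fixed seed and
independent of input row order; matching additionally uses per-case
substreams keyed by (seed, disorder, case rank in index-date order), so
adding or reordering cases does not perturb other cases' samples.

`expected_estimands()` enumerates the injected amounts over realised case
person-years. Given the matched sets it also subtracts the injections
carried by sampled controls (a control may be a case of another disorder,
or be diagnosed with the index disorder after the index date), yielding the
exact conditional expectation of the case-minus-control estimator; the
remaining discrepancy in any test is pure sampling noise, quantified by
`mc_se`.

What the generator does **not** emulate: correlated comorbidity (real
disorders co-occur far above independence), cost–mortality dependence,
income dynamics (careers, unemployment spells), regional tariff variation,
and under-ascertainment of mild cases treated outside hospitals. Passing
tests therefore demonstrate that the pipeline recovers known effects under
a faithful but simplified data-generating process — not that real-world
excess costs are unbiased causal effects, which the matched design cannot
promise in any case.

## Problem sizes and tolerances in the test suite

Unit tests run on hand-built fixtures and an 800-person bundle; oracle
equivalence uses a 100-person bundle with inflated hazards and asserts
agreement with naive loop-based recomputation to 1e-9 relative. The
study-level checks use 20,000 persons (matching validity; null recovery,
where every excess estimand with at least 500 case person-years must lie
within 3 standard errors of zero) and 50,000 persons (parameter recovery
within 10% of the enumerated truth and decay-ratio recovery), at a fixed
seed. These sizes give the null and recovery checks real statistical power
while keeping a full run of the suite within a coffee break on one CPU.

## Known limitations

* The bundled ICD-10 code sets and earliest onset ages are plausible
  GBD-style placeholders; any serious analysis must supply its own
  catalogue file (the loader validates structure, uniqueness and the union
  aggregate).
* The bundled deflator series and exchange rate are likewise defaults for
  synthetic work.
* No confidence intervals beyond the between-set `mc_se`; no adjustment
  for confounding; excess costs are associations.
* Deficient matched sets are retained rather than re-sampled with
  replacement; in small populations per-case estimates for rare disorders
  rest on few sets, and `n_sets` should be inspected.
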