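---
title: "Methods: medication-based comorbidity scoring from pharmacy claims"
author: "rxcomorbid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: medication-based comorbidity scoring from pharmacy claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Administrative pharmacy-claims databases record what was dispensed, not what
was diagnosed. When no clinical diagnoses are available, chronic disease
burden can still be inferred from medication classes: the RxRiskV family of
comorbidity indices maps WHO Anatomical Therapeutic Chemical (ATC) drug
codes to treated chronic conditions and scores a patient by the number of
distinct conditions treated. `rxcomorbid` implements a modified variant of
that index for monthly-collated claims in an elderly (65+) population, with
medication-treated type 2 diabetes (T2DM) as the index disease:

* T2DM status is a **proxy**: chronic dispensing of any oral
  anti-hyperglycaemic agent (ATC `A10B*`), alone or with insulin (`A10A*`).
  Insulin-only patients are *not* flagged (the proxy cannot separate type 1
  from diet-treated type 2), and diabetes itself is excluded from the index
  because it is the disease of interest.
* Comorbidity burden is the count of index conditions treated chronically,
  compared between the T2DM and non-T2DM groups by medians, by an
  age/sex-adjusted logistic odds ratio per condition, and by bootstrapped
  annual ingredient cost.

## The catalog and matching semantics

The shipped catalog (`rxriskv_mod_2010`) contains 42 condition categories,
each a set of ATC include patterns, optional exclude patterns, and (for
chronic heart failure only) *all-of* component groups. Matching rules:

* Patterns of 3–6 characters are hierarchy **prefixes**; 7-character
  patterns are exact codes. Queries must always be full 7-character codes.
* **Exclusion dominates**: a code under any exclude pattern never matches,
  whatever the includes say (e.g. a handful of sedating-antihistamine codes
  are carved out of the allergy category).
* **Chronic heart failure** is assigned only when *both* component groups —
  loop diuretics and ACE inhibitors — independently satisfy the chronicity
  rule. Component matching is done on raw codes *before* priority
  resolution, otherwise the resolution step could make the category
  unreachable.

A medication licensed for several indications must count once. Every
distinct code a patient receives is resolved to the **single
highest-priority matching category**. The source index does not publish its
ranking, so the shipped one is an explicit, editable total order (1–42)
placing clinically specific/severe categories first (transplant, HIV,
malignancies, …) and symptomatic therapy classes last (anti-inflammatories,
opiates). Changing the order is a data edit, not a code change.

Three printed code literals in the source list violate the ATC grammar
(`NO2AX05`, `N0BC09`, `NO2BA01` — letter O for zero, or a dropped digit).
The catalog stores them verbatim in a non-matching field — `lint_catalog()`
always flags them — and adds the plausibly intended codes (`N02AX05`,
`N04BC09`, `N02BA01`) as ordinary patterns behind `corrected = TRUE`
(default). One printed range spans chemical subgroups (`C01BA01-C01BD01`);
it is expanded hierarchically (prefixes `C01BA`, `C01BB`, `C01BC` plus exact
`C01BD01`). `V07AN`/`V07AS` are kept as printed although they are not
standard medicinal ATC codes.

## The chronicity rule

Claims are collated monthly, so the calendar month is the native time unit.
A category is assigned when the patient filled a prescription resolving to
it in at least `min_consecutive = 3` **consecutive calendar months**
(year boundaries are ordinary month steps). Codes within a category are
pooled: switching statins month to month still counts as continuous
treatment of hyperlipidemia. Same-month refills collapse to one
month-presence for chronicity, but each dispensing keeps its own cost. The
16-month default window (November 2009 – February 2011) pads the cost year
2010 by two months on each side so that three-month runs straddling the
year's edges remain observable.

The default cohort denominator keeps patients with at least one chronic
(three-consecutive-month) run of *any* medication, mirroring the source
population definition; `inclusion = "any_dispensing"` or `"all"` relax it.

## Statistical choices

* **Quartiles** are lower-interpolation (type 1), so reported medians and
  IQR bounds are attainable integer scores.
* **Scores of 10 or more** are pooled into one `">=10"` band (the published
  convention; under 1% of patients sit there).
* The **low/high split** threshold is the T2DM-group median; low is
  `< median`, high is `>= median`. Association uses Pearson's chi-square
  without continuity correction, plus an age/sex-adjusted logistic odds
  ratio for "high".
* **Per-condition odds ratios** come from one logistic model per condition
  (outcome = condition presence; predictors = T2DM, age band with reference
  65–69, sex with reference female), reported as exp(coefficient) with Wald
  95% intervals. No small-sample correction, no multiple-testing
  adjustment, matching the source's reporting. Conditions are filtered at
  10% whole-cohort prevalence by default. Perfect separation is flagged
  rather than estimated; covariates constant in the data are dropped, which
  reduces the estimate to the 2×2 cross-product ratio.
* **Percentages** print half-up to 1 decimal; ORs, CIs and cost ratios
  half-up to 2 decimals; p-values below 0.0001 print as `<0.0001`. Half-up
  rounding adds a 1e-9 epsilon to absorb binary-representation error.
* The chi-square over the full band distribution drops bands unoccupied in
  both groups, so `df = occupied bands − 1` (10 when all 11 bands occur).

## Costs

Annual ingredient cost sums, over the cost year only, the dispensings whose
resolved category is in the patient's *assigned* set: sub-chronic or
unmatched dispensings, and index-disease therapy (`A10A*`/`A10B*`), carry no
comorbidity cost. Every cohort member appears in the denominator, including
zero-condition patients at cost 0.

Costs are right-skewed, so group means are compared by bootstrap: resample
patients with replacement (2000 replicates by default), take the 2.5th and
97.5th empirical percentiles of the replicate means. The percentile method
is the simplest defensible variant given that the source names none; it is
the one to swap out first if bias-corrected intervals are ever needed.
Stratified tables bootstrap within stratum, with per-stratum seeds derived
from the base seed; given a seed, results are bit-reproducible and the
caller's RNG state is untouched. The cost ratio is T2DM mean over non-T2DM
mean, computed before rounding; a 0/0 stratum reports ratio 1.

## The synthetic cohort generator

No public claims data exists at this scale, so the generator is a
first-class module with known ground truth. Per patient: sex (43% male) and
age band (22.8 / 26.9 / 50.3%) are sampled; the T2DM flag uses the six
sex-by-age prevalences implied by the published stratified counts (overall
9.7%); each condition is then Bernoulli with logit = logit(baseline) +
log(OR)·T2DM — i.e. conditions are **conditionally independent given T2DM,
age and sex**, the estimand of the per-condition logistic models. Treated
conditions emit their representative code as a chronic run (start in the
first four window months, through the window's end) with probability
`persistence`, else a 1–2 month sub-chronic run that the chronicity filter
must reject. Heart failure emits its loop-diuretic and ACE-inhibitor codes
jointly. Per-dispensing ingredient costs are gamma (default mean €18, shape
1.5 — right-skewed, coefficient of variation ≈ 0.8, giving per-condition
annual costs in the low hundreds of euro as printed cost tables suggest).

Defaults that are package decisions rather than published facts:

* **Persistence defaults to 1.** Recovery of the planted odds ratios
  through the full pipeline is only achievable when condition presence is
  measured without chronicity misclassification; sub-chronic noise
  (persistence < 1) is a stress setting for the chronicity filter, not part
  of the default stated world.
* **A background filler code** (`A11GA01`, matching no category) is
  dispensed as a 3-month run to every patient. Near-universal repeat
  prescribing is realistic in an elderly medical-card population, and it
  keeps the default denominator non-selective — without it, zero-condition
  non-T2DM patients drop out of the cohort and visibly attenuate every
  planted odds ratio.
* **Sixteen background categories** (anxiety, gout, hypothyroidism, … at
  baseline prevalence 0.08 and T2DM OR 0.8452 each) supplement the ten
  published ≥10%-prevalence conditions. The pair (0.08, 0.8452) was solved
  once, from the exact Poisson–binomial count distribution, so that the
  implied odds ratio of a high count (≥ 5 conditions) is 2.80 — the
  documented planted value for the high/low split — with a stable T2DM
  median of 5. Under the independence assumption the count distribution is
  under-dispersed (variance ≤ mean − Σpᵢ²), which makes the published
  median pair (5 vs 3) incompatible with a split OR of 2.8: a non-T2DM
  median of 3 caps P(≥5 | non-T2DM) near 0.28, forcing P(≥5 | T2DM) onto
  the knife edge of 0.5. The calibration therefore fixes the split OR and
  the T2DM median and accepts a non-T2DM median of 4. Real claims data has
  positively correlated conditions (heavier count tails at a given median);
  that correlation is deliberately out of the generator's scope.

What a green test on synthetic data does **not** establish: realism of
drug-switching, market shares, dispensing volumes, within-patient condition
correlation, seasonal dispensing patterns, or cost differences between drug
classes. The generator validates the *pipeline machinery* — matching,
resolution, chronicity, aggregation, model recovery — not the epidemiology.

## Degenerate inputs and edge behaviour

Empty claim sets score zero; empty cohorts error in the prevalence table
and report `n = 0` strata elsewhere; a one-sided low/high split reports a
degenerate chi-square rather than a number; bootstrap of a constant vector
returns a degenerate interval; truncated ATC query codes are always an
error (patterns may be truncated, queries may not).

## Known limitations

* The priority ranking is a stand-in for an unpublished ordering; results
  for multi-indication codes depend on it.
* Two of the published index's 45 original categories are not printed in
  the source list (diabetes is a third, deliberately excluded); the shipped
  catalog is exactly the 42 printed.
* No dose/duration (DDD) logic, no ICD mapping, no severity weights, no
  adherence metrics, and costs are ingredient-only (no fees or co-payments).
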