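# rxcomorbid

Medication-based comorbidity scoring and ingredient-cost analysis for
monthly pharmacy dispensing claims, built around a modified RxRiskV index
with medication-treated type 2 diabetes (T2DM) as the index disease.

Pharmacy-claims databases record dispensings, not diagnoses. For
pharmacoepidemiologists working with such data, `rxcomorbid` provides the
full inference chain:

1. **Catalog** — 42 chronic-condition categories defined by WHO ATC code
   patterns (prefix and exact), with exclusion lists, an all-of rule for
   chronic heart failure (loop diuretic **and** ACE inhibitor), and a
   priority ranking that assigns multi-indication drugs to a single
   category. Includes a linter for ambiguous or non-conforming entries.
2. **Scoring** — the chronicity rule: a condition is attributed only after
   dispensings of its medication class in ≥ 3 consecutive calendar months.
   T2DM is flagged by chronic oral anti-hyperglycaemic dispensing
   (ATC `A10B*`; insulin alone does not count). The comorbidity score is
   the count of assigned conditions, capped into a `>=10` band.
3. **Statistics** — stratified T2DM prevalence; median/IQR tables (type-1
   integer quartiles); low-vs-high comorbidity split at the T2DM-group
   median with Pearson χ²; per-condition odds ratios adjusted for age
   (ref 65–69) and sex (ref female) with Wald 95% CIs.
4. **Costs** — annual ingredient cost per patient over the assigned
   categories, compared across groups by percentile bootstrap
   (2000 replicates by default), stratified by sex, age, and comorbidity
   count, with T2DM / non-T2DM cost ratios.
5. **Synthetic cohort** — a seed-deterministic claims generator with known
   ground truth (planted prevalences, odds ratios, skewed gamma costs), so
   the whole pipeline is testable without access to confidential claims.

For a patient *i* with dispensing months *M(c)* per resolved category *c*,
the score is

    score_i = | { c : longest-consecutive-run(M_i(c)) >= 3 } |

and the per-condition association model is

    logit P(condition) = b0 + b1·T2DM + b2·age70-74 + b3·age75+ + b4·male,
    adjusted OR = exp(b1).

## Worked example

```r
library(rxcomorbid)

catalog <- load_catalog("rxriskv_mod_2010")
#> <rx_catalog 'rxriskv_mod_2010': 42 categories>
categories_for_code(catalog, "C10AA05")
#> [1] "Hyperlipidemia"

cfg  <- paper_marginals_config(n_patients = 10000L)
sim  <- generate_cohort(cfg, seed = 1)
prof <- score_cohort(sim$claims, sim$demographics, catalog)

pv <- prevalence_table(prof)
#> T2DM prevalence: 9.6% (959 of 10000)

median_iqr_table(prof)   # pooled rows shown
#>    sex age_band    group    n median_score q1 q3
#>    all      all     t2dm  959            5  4  6
#>    all      all non_t2dm 9041            4  3  5

hl <- high_low_split(prof)
#> high-comorbidity (>=5) adjusted OR: 2.45 [2.14, 2.80]

adjusted_odds_ratios(prof)  # first rows
#>                condition prevalence_non_pct prevalence_t2dm_pct odds_ratio
#>           Hyperlipidemia               41.9                79.0       5.22
#>    Anti-platelet therapy               40.0                68.8       3.31
#>            Heart disease               39.8                61.2       2.38

ac  <- annual_costs(sim$claims, prof, catalog, cfg$window)
tab <- cost_table(ac, prof, replicates = 500, seed = 17)
#> male 65-69: mean_t2dm 975.31, mean_non 816.95, cost_ratio 1.19
```

Read: in this 10,000-patient synthetic cohort, 9.6% are flagged as
medication-treated T2DM (planted: 9.7%); they carry a median of 5 treated
chronic conditions against 4 without T2DM; their odds of high comorbidity
(≥ 5 conditions) are 2.45 times higher (planted: 2.80, inside the CI);
hyperlipidemia is the condition most strongly associated with T2DM
(OR 5.22; planted 4.95); and their annual comorbidity ingredient cost runs
about 1.2 times higher. Estimates sharpen toward the planted values at the
default 100,000-patient scale.

The command-line front end wraps the same steps:

```sh
Rscript inst/cli/rxcomorbid simulate --n 10000 --seed 1 --out-dir sim/
Rscript inst/cli/rxcomorbid score --claims sim/claims.csv \
    --demographics sim/demographics.csv --out profiles.csv
Rscript inst/cli/rxcomorbid tables --profiles profiles.csv --out-dir results/
Rscript inst/cli/rxcomorbid costs --claims sim/claims.csv \
    --profiles profiles.csv --seed 17 --out results/table3.csv
Rscript inst/cli/rxcomorbid catalog match C10AA05
```

## Data model

Claims are comma-delimited text with header
`patient_id,month,atc_code,ingredient_cost` (months as `YYYY-MM`; claims are
collated monthly, so the month is the native resolution); demographics are
`patient_id,sex,age_band` with bands `65-69`, `70-74`, `>=75`. The default
study window is 2009-11 through 2011-02 (16 months) with costs summed over
2010. See the methods vignette (`vignettes/rxcomorbid-methods.Rmd`) for the
modelling choices, the generator's calibration, and known limitations.
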