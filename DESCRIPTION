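Package: rxcomorbid
Title: Medication-Based Comorbidity Scoring and Cost Analysis from Pharmacy Claims
Version: 0.1.0
Authors@R:
    person("PCRS", "Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies monthly pharmacy dispensing claims into chronic-condition
    categories of the RxRiskV (mod) medication-based comorbidity index via WHO ATC
    codes, identifies medication-treated type 2 diabetes by proxy (chronic oral
    anti-hyperglycaemic dispensing), and produces stratified comorbidity-burden
    summaries, age- and sex-adjusted odds ratios, and bootstrapped annual
    ingredient-cost comparisons. Includes a seed-deterministic synthetic claims
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
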