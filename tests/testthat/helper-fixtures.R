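# In-code fixtures: miniature catalogs, claims and profile builders.

mini_catalog_json <- function(categories) {
  tf <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(version = "test", categories = categories),
                              auto_unbox = TRUE), tf)
  tf
}

mini_cat <- function(name, includes, excludes = character(),
                     all_of_groups = list(), priority_rank = 1L,
                     concordant = FALSE, verbatim_literals = character(),
                     corrected_codes = character()) {
  list(name = name, includes = as.list(includes),
       excludes = as.list(excludes),
       all_of_groups = lapply(all_of_groups, as.list),
       verbatim_literals = as.list(verbatim_literals),
       corrected_codes = as.list(corrected_codes),
       priority_rank = priority_rank, concordant = concordant)
}

make_claims <- function(patient_id, months, codes, costs = 1) {
  data.table::data.table(patient_id = patient_id, month = months,
                         atc_code = codes, ingredient_cost = costs)
}

make_demo <- function(ids, sex = "female", age_band = "65-69") {
  data.table::data.table(patient_id = ids, sex = sex, age_band = age_band)
}

# profiles table built directly (for the stats modules)
make_profiles <- function(raw_score, t2dm, sex = "female",
                          age_band = "65-69", conditions = NULL) {
  n <- length(raw_score)
  data.table::data.table(
    patient_id = sprintf("P%05d", seq_len(n)),
    sex = factor(rep_len(sex, n), c("female", "male")),
    age_band = factor(rep_len(age_band, n), c("65-69", "70-74", ">=75")),
    t2dm = rep_len(t2dm, n),
    raw_score = as.integer(raw_score),
    capped_band = factor(ifelse(raw_score >= 10, ">=10",
                                as.character(raw_score)),
                         c(as.character(0:9), ">=10")),
    conditions = if (is.null(conditions)) "" else rep_len(conditions, n))
}

# pool of full codes touching many shipped categories, plus index-drug and
# unmatched codes, for random micro-cohorts
micro_code_pool <- c(
  "C10AA05", "C10AA01", "B01AC06", "C07AB02", "C03AA03", "A02BC01",
  "N06AB04", "R03AC02", "M05BA04", "M01AE01", "N02AA01", "N05BA01",
  "M04AA01", "H03AA01", "C03CA01", "C09AA02", "N05AN01", "N06DA02",
  "R06AX27", "R06AX02", "A10BA02", "A10AB01", "A11GA01", "V01AA01",
  "N02AX05", "J05AB54", "V07AN01", "B03XA01")

random_micro_cohort <- function(n_patients, n_records) {
  months <- index_to_month_vec(24118:24133)  # 2009-11..2011-02
  data.table::data.table(
    patient_id = sprintf("M%02d", sample.int(n_patients, n_records,
                                             replace = TRUE)),
    month = sample(months, n_records, replace = TRUE),
    atc_code = sample(micro_code_pool, n_records, replace = TRUE),
    ingredient_cost = round(runif(n_records, 1, 40), 2))
}

index_to_month_vec <- function(idx) {
  sprintf("%04d-%02d", idx %/% 12L, idx %% 12L + 1L)
}
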