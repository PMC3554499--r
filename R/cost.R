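# Annual ingredient-cost aggregation and percentile-bootstrap comparison of
# means. Costs are attributed only to dispensings whose code resolves (post
# priority resolution) to a category the patient was actually assigned;
# sub-chronic or unmatched dispensings, and index-disease therapy (A10A/A10B),
# carry no comorbidity cost.

#' Annual comorbidity ingredient costs per patient
#'
#' Sums ingredient costs over the cost year of the window, restricted to
#' dispensings whose resolved category is in the patient's assigned condition
#' set. Every profile row is represented; patients with no assigned
#' conditions total 0.
#'
#' @param claims dispensing records.
#' @param profiles output of [score_cohort()] computed from the same claims.
#' @param catalog the `rx_catalog` used for scoring.
#' @param window the [study_window()]; only months of `window$cost_year`
#'   contribute.
#' @return `data.table`: `patient_id`, `total_cost`, plus attribute
#'   `per_category` (long `data.table` patient_id/category/cost).
#' @export
annual_costs <- function(claims, profiles, catalog, window = study_window()) {
  prof <- data.table::as.data.table(profiles)
  unknown <- setdiff(unique(claims$patient_id), prof$patient_id)
  # claims from patients outside the scored cohort are ignored (they failed
  # the inclusion rule); a patient never scored at all is an error
  dt <- data.table::data.table(pid = claims$patient_id,
                               midx = month_to_index(claims$month),
                               code = toupper(claims$atc_code),
                               cost = claims$ingredient_cost)
  dt <- dt[!(pid %in% unknown)]
  dt <- dt[midx %/% 12L == window$cost_year]
  cmap <- resolve_code_map(dt$code, catalog)
  dt <- merge(dt, cmap, by.x = "code", by.y = "atc_code", sort = FALSE)
  dt <- dt[!is.na(category)]
  # keep only (patient, category) pairs present in the assigned sets
  assigned <- prof[nzchar(conditions),
                   .(category = strsplit(conditions, ";", fixed = TRUE)[[1L]]),
                   by = .(pid = patient_id)]
  dt <- merge(dt, assigned, by = c("pid", "category"), sort = FALSE)
  per_cat <- dt[, .(cost = sum(cost)), by = .(patient_id = pid, category)]
  tot <- per_cat[, .(total_cost = sum(cost)), by = patient_id]
  out <- merge(prof[, .(patient_id)], tot, by = "patient_id", all.x = TRUE)
  out[is.na(total_cost), total_cost := 0]
  data.table::setorder(out, patient_id)
  data.table::setattr(out, "per_category", per_cat)
  out[]
}

#' Percentile-bootstrap mean with 95% CI
#'
#' Resamples `costs` with replacement `replicates` times; the CI is the
#' empirical 2.5th/97.5th percentile of the replicate means (type-1
#' quantiles), the point estimate the plain sample mean. Skewed cost data is
#' the motivating case. With a `seed` the result is reproducible and the
#' caller's RNG state is left untouched.
#'
#' @param costs numeric vector, non-empty.
#' @param replicates bootstrap replicates (2000 in the reference analysis).
#' @param seed optional integer seed.
#' @return list: `mean`, `ci95` (length 2), `replicates`, `seed`.
#' @examples
#' bootstrap_mean(c(5, 5, 5, 5), replicates = 100, seed = 1)$ci95  # c(5, 5)
#' @export
bootstrap_mean <- function(costs, replicates = 2000L, seed = NULL) {
  if (!length(costs)) stop("empty cost vector", call. = FALSE)
  stopifnot(is.numeric(costs), all(is.finite(costs)))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  n <- length(costs)
  means <- vapply(seq_len(replicates), function(i)
    mean(costs[sample.int(n, n, replace = TRUE)]), 0)
  list(mean = mean(costs),
       ci95 = unname(quantile(means, c(0.025, 0.975), type = 1)),
       replicates = as.integer(replicates), seed = seed)
}

#' Ratio of group means, half-up to 2 decimals
#'
#' Convention: T2DM mean over non-T2DM mean, computed before any rounding of
#' the means; two zero means give ratio 1 (the zero-condition stratum).
#'
#' @param mean_t2dm,mean_non numeric scalars.
#' @return numeric scalar.
#' @examples
#' cost_ratio(1183.43, 683.85)  # 1.73
#' @export
cost_ratio <- function(mean_t2dm, mean_non) {
  if (mean_non == 0 && mean_t2dm == 0) return(1)
  round_half_up(mean_t2dm / mean_non, 2)
}

#' Stratified bootstrap cost table
#'
#' Bootstrap mean and 95% CI per sex-by-age-by-group stratum and per capped
#' comorbidity-count band by group, with the T2DM / non-T2DM cost ratio per
#' stratum (ratio of point estimates, before rounding). Bootstrapping is
#' within stratum with a per-stratum seed derived from `seed`. Empty strata
#' yield `NA` cells.
#'
#' @param costs output of [annual_costs()].
#' @param profiles matching profiles.
#' @param replicates bootstrap replicates per stratum.
#' @param seed base integer seed.
#' @return `data.table`: `stratum_type` (`"sex_age"`/`"n_conditions"`),
#'   `sex`, `age_band`, `band`, then per group `n`, `mean`, `ci_low`,
#'   `ci_high`, and `cost_ratio`.
#' @export
cost_table <- function(costs, profiles, replicates = 2000L, seed = 17L) {
  p <- merge(data.table::as.data.table(profiles),
             data.table::as.data.table(costs), by = "patient_id")
  p[, group := ifelse(t2dm, "t2dm", "non_t2dm")]

  strata <- rbind(
    data.table::CJ(stratum_type = "sex_age", sex = .sex_levels,
                   age_band = .age_levels, band = NA_character_),
    data.table::CJ(stratum_type = "n_conditions", sex = NA_character_,
                   age_band = NA_character_, band = .capped_levels))

  one_group <- function(x, s) {
    if (!length(x)) return(list(n = 0L, mean = NA_real_, lo = NA_real_,
                                hi = NA_real_))
    b <- bootstrap_mean(x, replicates, seed = s)
    list(n = length(x), mean = b$mean, lo = b$ci95[1], hi = b$ci95[2])
  }

  rows <- lapply(seq_len(nrow(strata)), function(i) {
    st <- strata[i]
    sub <- if (st$stratum_type == "sex_age") {
      p[sex == st$sex & age_band == st$age_band]
    } else {
      p[as.character(capped_band) == st$band]
    }
    g1 <- one_group(sub[group == "t2dm", total_cost], seed + 2L * i)
    g0 <- one_group(sub[group == "non_t2dm", total_cost], seed + 2L * i + 1L)
    data.table::data.table(
      st,
      n_t2dm = g1$n, mean_t2dm = g1$mean,
      ci_low_t2dm = g1$lo, ci_high_t2dm = g1$hi,
      n_non = g0$n, mean_non = g0$mean,
      ci_low_non = g0$lo, ci_high_non = g0$hi,
      cost_ratio = if (g1$n && g0$n) cost_ratio(g1$mean, g0$mean) else NA_real_)
  })
  data.table::rbindlist(rows)
}
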