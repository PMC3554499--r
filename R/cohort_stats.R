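# Stratified prevalence, comorbidity-distribution and adjusted-odds-ratio
# analytics over scored profiles.

#' Half-up rounding
#'
#' Commercial (half-away-from-zero) rounding, used for all printed
#' percentages (1 decimal) and odds ratios / cost ratios (2 decimals);
#' base R's `round()` rounds half to even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # epsilon guards against values stored infinitesimally below a half
  sign(x) * trunc(abs(x) * p + 0.5 + 1e-9) / p
}

.pct <- function(num, den) round_half_up(100 * num / den, 1)

#' Prevalence marginals from stratum counts
#'
#' Consistency checker over a 12-cell sex-by-age-by-group count table (the
#' shape of a stratified cohort table): recomputes every marginal — overall
#' T2DM prevalence, prevalence by sex and by age band, group totals, and age
#' shares. Percentages are half-up to 1 decimal; counts are exact.
#'
#' @param counts data.frame with columns `sex` (`male`/`female`), `age_band`
#'   (`65-69`, `70-74`, `>=75`), `group` (`t2dm`/`non_t2dm`), `n`.
#' @return list with `n_total`, `n_t2dm`, `n_non_t2dm`, `n_male`, `n_female`,
#'   `prevalence_overall_pct`, `prevalence_by_sex_pct`,
#'   `prevalence_by_age_pct`, `age_share_pct` (all percentage entries
#'   half-up, 1 decimal).
#' @examples
#' counts <- read.csv(system.file("extdata", "table1_stratum_counts.csv",
#'                                package = "rxcomorbid"))
#' prevalence_from_counts(counts)$prevalence_overall_pct  # 9.7
#' @export
prevalence_from_counts <- function(counts) {
  counts <- data.table::as.data.table(counts)
  stopifnot(all(c("sex", "age_band", "group", "n") %in% names(counts)),
            all(counts$group %in% c("t2dm", "non_t2dm")),
            all(counts$n >= 0))
  tot <- sum(counts$n)
  if (tot == 0) stop("empty cohort", call. = FALSE)
  n_t2dm <- counts[group == "t2dm", sum(n)]
  by_sex <- counts[, .(n_t2dm = sum(n[group == "t2dm"]), n = sum(n)), by = sex]
  by_age <- counts[, .(n_t2dm = sum(n[group == "t2dm"]), n = sum(n)),
                   by = age_band]
  list(
    n_total = tot,
    n_t2dm = n_t2dm,
    n_non_t2dm = tot - n_t2dm,
    n_male = by_sex[sex == "male", n],
    n_female = by_sex[sex == "female", n],
    prevalence_overall_pct = .pct(n_t2dm, tot),
    prevalence_by_sex_pct = setNames(.pct(by_sex$n_t2dm, by_sex$n), by_sex$sex),
    prevalence_by_age_pct = setNames(.pct(by_age$n_t2dm, by_age$n),
                                     by_age$age_band),
    age_share_pct = setNames(.pct(by_age$n, tot), by_age$age_band))
}

profiles_to_counts <- function(profiles) {
  p <- data.table::as.data.table(profiles)
  p[, .(n = .N), by = .(sex, age_band,
                        group = ifelse(t2dm, "t2dm", "non_t2dm"))]
}

#' Stratified T2DM prevalence of a scored cohort
#'
#' @param profiles output of [score_cohort()].
#' @return as [prevalence_from_counts()].
#' @export
prevalence_table <- function(profiles) {
  if (!nrow(profiles)) stop("empty cohort", call. = FALSE)
  prevalence_from_counts(profiles_to_counts(profiles))
}

# lower-interpolation (type-1) quartiles: attainable integers on integer data
.q1q2q3 <- function(x) unname(quantile(x, c(0.25, 0.5, 0.75), type = 1))

#' Median and IQR of comorbidity score by stratum
#'
#' Per sex-by-age-by-group stratum plus pooled per-group rows. Quartiles use
#' lower interpolation (type 1) so medians and IQR bounds are attainable
#' integer scores. Empty strata are reported with `n = 0` and `NA` quantiles.
#'
#' @param profiles output of [score_cohort()].
#' @return `data.table`: `sex`, `age_band` (`"all"` for pooled rows),
#'   `group`, `n`, `median_score`, `q1`, `q3`.
#' @export
median_iqr_table <- function(profiles) {
  p <- data.table::as.data.table(profiles)
  p[, group := ifelse(t2dm, "t2dm", "non_t2dm")]
  grid <- data.table::CJ(sex = .sex_levels, age_band = .age_levels,
                         group = c("t2dm", "non_t2dm"))
  strat <- p[, .(n = .N, median_score = .q1q2q3(raw_score)[2],
                 q1 = .q1q2q3(raw_score)[1], q3 = .q1q2q3(raw_score)[3]),
             by = .(sex = as.character(sex), age_band = as.character(age_band),
                    group)]
  strat <- merge(grid, strat, by = c("sex", "age_band", "group"), all.x = TRUE)
  strat[is.na(n), n := 0L]
  pooled <- p[, .(sex = "all", age_band = "all", n = .N,
                  median_score = .q1q2q3(raw_score)[2],
                  q1 = .q1q2q3(raw_score)[1], q3 = .q1q2q3(raw_score)[3]),
              by = group]
  out <- rbind(strat, pooled[, names(strat), with = FALSE])
  data.table::setorder(out, sex, age_band, -group)
  out[]
}

# age/sex-adjusted logistic model; returns OR for the T2DM term with Wald CI
.adjusted_or <- function(outcome, profiles) {
  dat <- data.frame(y = outcome, t2dm = profiles$t2dm,
                    age_band = droplevels(profiles$age_band),
                    sex = droplevels(profiles$sex))
  # covariates constant in the data drop out of the model (they are then
  # inestimable, and the adjusted OR reduces to the cross-product ratio)
  terms <- c("t2dm",
             if (nlevels(dat$age_band) > 1L) "age_band",
             if (nlevels(dat$sex) > 1L) "sex")
  fml <- stats::reformulate(terms, response = "y")
  fit <- suppressWarnings(glm(fml, family = binomial(), data = dat))
  co <- coef(summary(fit))["t2dmTRUE", ]
  est <- co[["Estimate"]]; se <- co[["Std. Error"]]
  separated <- !fit$converged || se > 10 || abs(est) > 10
  z <- qnorm(0.975)
  list(or = exp(est), ci_low = exp(est - z * se), ci_high = exp(est + z * se),
       p = co[["Pr(>|z|)"]], separated = separated)
}

#' Low-versus-high comorbidity split
#'
#' The T2DM-group median score is the threshold: low `< median`, high
#' `>= median`. Reports the 2x2 contingency table, the Pearson chi-square
#' without continuity correction, and the age/sex-adjusted odds ratio of
#' high comorbidity for T2DM (Wald 95% CI).
#'
#' @param profiles output of [score_cohort()].
#' @return list with `threshold`, `table` (2x2 group-by-level counts),
#'   `chi_square` (`statistic`, `df`, `p`; `NA` with `degenerate = TRUE`
#'   when a margin is empty), and `adjusted_or`.
#' @export
high_low_split <- function(profiles) {
  p <- data.table::as.data.table(profiles)
  t2 <- p[t2dm == TRUE, raw_score]
  if (!length(t2)) stop("T2DM-group median not computable: no T2DM patients",
                        call. = FALSE)
  thr <- .q1q2q3(t2)[2]
  high <- p$raw_score >= thr
  tab <- table(group = factor(ifelse(p$t2dm, "t2dm", "non_t2dm"),
                              c("non_t2dm", "t2dm")),
               level = factor(ifelse(high, "high", "low"), c("low", "high")))
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  chi <- if (degenerate) {
    list(statistic = NA_real_, df = NA_integer_, p = NA_real_, degenerate = TRUE)
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    list(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p = unname(ct$p.value), degenerate = FALSE)
  }
  aor <- if (degenerate) NULL else .adjusted_or(high, p)
  list(threshold = thr, table = tab, chi_square = chi, adjusted_or = aor)
}

#' Comorbidity-count distribution chi-square
#'
#' Pearson chi-square over the capped-band (0..9, `>=10`) by group
#' contingency table; bands unoccupied in both groups are dropped, so
#' `df = occupied bands - 1`.
#'
#' @param profiles output of [score_cohort()].
#' @return list: `counts` (bands x 2 matrix), `statistic`, `df`, `p`.
#' @export
distribution_chi_square <- function(profiles) {
  p <- data.table::as.data.table(profiles)
  tab <- table(band = p$capped_band,
               group = factor(ifelse(p$t2dm, "t2dm", "non_t2dm"),
                              c("non_t2dm", "t2dm")))
  if (any(colSums(tab) == 0)) {
    stop("both T2DM and non-T2DM groups must be non-empty", call. = FALSE)
  }
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(counts = unclass(tab), statistic = unname(ct$statistic),
       df = unname(ct$parameter), p = unname(ct$p.value))
}

condition_indicators <- function(profiles, conditions = NULL) {
  sets <- strsplit(profiles$conditions, ";", fixed = TRUE)
  if (is.null(conditions)) {
    conditions <- sort(unique(unlist(sets, use.names = FALSE)))
    conditions <- conditions[nzchar(conditions)]
  }
  out <- vapply(conditions, function(cn)
    vapply(sets, function(s) cn %in% s, NA), logical(nrow(profiles)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(profiles),
                                       dimnames = list(NULL, conditions))
  out
}

#' Adjusted odds ratios per comorbid condition
#'
#' One logistic model per condition: outcome = condition presence,
#' predictors = T2DM flag, age band (reference 65-69) and sex (reference
#' female). Reports the exponentiated T2DM coefficient with a Wald 95% CI.
#' Conditions are filtered at a whole-cohort prevalence threshold (default
#' 10%). Perfectly separated models are flagged and carry no estimate.
#'
#' @param profiles output of [score_cohort()].
#' @param min_prevalence_pct whole-cohort prevalence filter, percent.
#' @param conditions optional explicit condition subset (filter still
#'   applies).
#' @return `data.table`: `condition`, `prevalence_non_pct`,
#'   `prevalence_t2dm_pct` (half-up, 1 decimal), `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_value`, `separated`.
#' @export
adjusted_odds_ratios <- function(profiles, min_prevalence_pct = 10,
                                 conditions = NULL) {
  p <- data.table::as.data.table(profiles)
  ind <- condition_indicators(p, conditions)
  prev <- colMeans(ind) * 100
  keep <- prev >= min_prevalence_pct
  if (!any(keep)) {
    return(data.table::data.table(
      condition = character(), prevalence_non_pct = numeric(),
      prevalence_t2dm_pct = numeric(), odds_ratio = numeric(),
      ci_low = numeric(), ci_high = numeric(), p_value = numeric(),
      separated = logical()))
  }
  ind <- ind[, keep, drop = FALSE]
  res <- lapply(colnames(ind), function(cn) {
    y <- ind[, cn]
    if (all(y) || !any(y)) {
      stop(sprintf("condition '%s' is present in all or no patients", cn),
           call. = FALSE)
    }
    a <- .adjusted_or(y, p)
    data.table::data.table(
      condition = cn,
      prevalence_non_pct = .pct(sum(y & !p$t2dm), sum(!p$t2dm)),
      prevalence_t2dm_pct = .pct(sum(y & p$t2dm), sum(p$t2dm)),
      odds_ratio = if (a$separated) NA_real_ else a$or,
      ci_low = if (a$separated) NA_real_ else a$ci_low,
      ci_high = if (a$separated) NA_real_ else a$ci_high,
      p_value = if (a$separated) NA_real_ else a$p,
      separated = a$separated)
  })
  out <- data.table::rbindlist(res)
  data.table::setorder(out, -odds_ratio, na.last = TRUE)
  out[]
}

#' Format a p-value the reporting way
#'
#' Values below 0.0001 print as `"<0.0001"`, otherwise 4 decimals.
#' @param p numeric vector of p-values.
#' @return character vector.
#' @export
format_p <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 1e-4, "<0.0001", sprintf("%.4f", p)))
}
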