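# Scoring engine: claims -> chronic conditions, T2DM proxy flag, comorbidity
# score. Chronicity = dispensings of a category's medication class in at
# least `min_consecutive` consecutive calendar months (codes within a
# category pooled, so switching statins month-to-month still counts).

.capped_levels <- c(as.character(0:9), ">=10")

#' Chronicity rule
#'
#' A condition is attributed only when its medication class was dispensed in
#' at least `min_consecutive` consecutive calendar months — the "three
#' consecutive prescriptions" reading of chronic therapy under monthly claims
#' collation.
#'
#' @param min_consecutive positive integer, default 3.
#' @return a `chronicity_rule` object.
#' @export
chronicity_rule <- function(min_consecutive = 3L) {
  min_consecutive <- as.integer(min_consecutive)
  stopifnot(length(min_consecutive) == 1L, min_consecutive >= 1L)
  structure(list(min_consecutive = min_consecutive), class = "chronicity_rule")
}

# Vectorised include/exclude match of many full codes against one category.
match_codes_category <- function(category, codes) {
  inc <- rep(FALSE, length(codes))
  for (p in category$includes) inc <- inc | startsWith(codes, p)
  if (length(category$excludes)) {
    exc <- rep(FALSE, length(codes))
    for (p in category$excludes) exc <- exc | startsWith(codes, p)
    inc <- inc & !exc
  }
  inc
}

# Resolution map: each distinct full ATC code -> the single highest-priority
# matching category (NA if none). Multi-indication medications are credited
# to one disease category only.
resolve_code_map <- function(codes, catalog) {
  codes <- unique(codes)
  res <- rep(NA_character_, length(codes))
  rank <- rep(Inf, length(codes))
  for (cat in catalog$categories) {
    hit <- match_codes_category(cat, codes) & cat$priority_rank < rank
    res[hit] <- cat$name
    rank[hit] <- cat$priority_rank
  }
  data.table::data.table(atc_code = codes, category = res)
}

# Longest consecutive-month run per group; expects columns pid, key, midx.
.runs_ge <- function(dt, min_run) {
  if (!nrow(dt)) {
    # note: data.table() would swallow a column literally named "key"
    empty <- data.table::data.table(pid = character(), k = character())
    return(data.table::setnames(empty, "k", "key"))
  }
  u <- unique(dt[, .(pid, key, midx)])
  data.table::setorder(u, pid, key, midx)
  u[, grp := midx - seq_len(.N), by = .(pid, key)]
  runs <- u[, .N, by = .(pid, key, grp)]
  unique(runs[N >= min_run, .(pid, key)])
}

# Core engine shared by assign_conditions / identify_t2dm / score_cohort.
# claims: data.table(patient_id, month, atc_code). Returns per-patient
# condition sets and T2DM flags for every patient present in the claims.
.score_claims <- function(claims, catalog, rule) {
  dt <- data.table::data.table(pid = claims$patient_id,
                               midx = month_to_index(claims$month),
                               code = toupper(claims$atc_code))
  if (anyNA(dt$midx)) stop("unparseable month in claims", call. = FALSE)

  min_run <- rule$min_consecutive

  # T2DM proxy: oral anti-hyperglycaemics (A10B*) pooled at class level;
  # insulin alone (A10A*) never qualifies.
  t2dm_ids <- .runs_ge(dt[startsWith(code, "A10B"),
                          .(pid, key = "t2dm", midx)], min_run)$pid

  # all-of categories (CHF): every component group must independently be
  # chronic, judged on raw code matches before priority resolution.
  allof_cats <- Filter(function(cat) length(cat$all_of_groups) > 0L,
                       catalog$categories)
  allof_assign <- list()
  for (cat in allof_cats) {
    sat <- NULL
    for (g in seq_along(cat$all_of_groups)) {
      pats <- cat$all_of_groups[[g]]
      hit <- rep(FALSE, nrow(dt))
      for (p in pats) hit <- hit | startsWith(dt$code, p)
      if (length(cat$excludes)) {
        for (p in cat$excludes) hit <- hit & !startsWith(dt$code, p)
      }
      ids <- .runs_ge(dt[hit, .(pid, key = "g", midx)], min_run)$pid
      sat <- if (is.null(sat)) ids else intersect(sat, ids)
      if (!length(sat)) break
    }
    allof_assign[[cat$name]] <- sat
  }
  allof_names <- names(allof_assign)

  # per-code priority resolution, then class-level chronicity per category
  cmap <- resolve_code_map(dt$code, catalog)
  dtc <- merge(dt, cmap, by.x = "code", by.y = "atc_code", sort = FALSE)
  dtc <- dtc[!is.na(category) & !(category %in% allof_names)]
  assigned <- .runs_ge(dtc[, .(pid, key = category, midx)], min_run)

  if (length(allof_names)) {
    extra <- data.table::rbindlist(lapply(allof_names, function(nm) {
      ids <- allof_assign[[nm]]
      dt_nm <- data.table::data.table(pid = ids, k = rep(nm, length(ids)))
      data.table::setnames(dt_nm, "k", "key")
    }))
    assigned <- rbind(assigned, extra)
  }

  list(conditions = assigned,           # data.table(pid, key = category)
       t2dm_ids = t2dm_ids,
       all_ids = unique(dt$pid),
       chronic_any_ids = .runs_ge(dt[, .(pid, key = "any", midx)], min_run)$pid)
}

#' Assign chronic conditions to one patient
#'
#' Applies multi-indication resolution (each distinct ATC code credited to
#' its single highest-priority matching category), the chronicity rule per
#' category with codes pooled, and the all-of rule for composite categories
#' (chronic heart failure requires a chronic loop diuretic *and* a chronic
#' ACE inhibitor, judged on raw code matches).
#'
#' @param claims dispensing records of a single patient (`data.table` with
#'   `patient_id`, `month`, `atc_code`).
#' @param catalog an `rx_catalog`.
#' @param rule a [chronicity_rule()].
#' @return sorted character vector of assigned category names (possibly
#'   empty).
#' @export
assign_conditions <- function(claims, catalog, rule = chronicity_rule()) {
  if (!nrow(claims)) return(character())
  if (length(unique(claims$patient_id)) > 1L) {
    stop("assign_conditions expects claims of a single patient", call. = FALSE)
  }
  sc <- .score_claims(claims, catalog, rule)
  sort(sc$conditions$key)
}

#' Medication-treated T2DM proxy flag
#'
#' `TRUE` when any oral anti-hyperglycaemic codes (ATC `A10B*`, pooled as a
#' class) satisfy the chronicity rule. Insulin-only therapy (`A10A*` with no
#' `A10B*`) does not qualify.
#'
#' @inheritParams assign_conditions
#' @return logical flag.
#' @export
identify_t2dm <- function(claims, rule = chronicity_rule()) {
  if (!nrow(claims)) return(FALSE)
  if (length(unique(claims$patient_id)) > 1L) {
    stop("identify_t2dm expects claims of a single patient", call. = FALSE)
  }
  dt <- data.table::data.table(pid = claims$patient_id,
                               midx = month_to_index(claims$month),
                               code = toupper(claims$atc_code))
  nrow(.runs_ge(dt[startsWith(code, "A10B"), .(pid, key = "t2dm", midx)],
                rule$min_consecutive)) > 0L
}

#' Score a cohort
#'
#' Produces one comorbidity profile per cohort member: the set of chronic
#' conditions, the raw score (count of conditions; the index disease never
#' contributes), the capped band (scores of 10+ pooled as `">=10"`), and the
#' T2DM proxy flag.
#'
#' @param claims dispensing records (all patients).
#' @param demographics demographics table covering every claims patient.
#' @param catalog an `rx_catalog`.
#' @param rule a [chronicity_rule()].
#' @param inclusion cohort denominator: `"chronic_any"` (default) keeps
#'   patients with at least one chronic (rule-satisfying) run of *any*
#'   medication — the "received at least three consecutive prescriptions"
#'   denominator; `"any_dispensing"` keeps patients with any record;
#'   `"all"` keeps every demographics row.
#' @return `data.table` with columns `patient_id`, `sex`, `age_band`,
#'   `t2dm`, `raw_score`, `capped_band`, `conditions` (semicolon-joined,
#'   alphabetical).
#' @export
score_cohort <- function(claims, demographics, catalog,
                         rule = chronicity_rule(),
                         inclusion = c("chronic_any", "any_dispensing", "all")) {
  inclusion <- match.arg(inclusion)
  demographics <- validate_demographics(demographics)
  if (nrow(demographics) == 0L) {
    return(data.table::data.table(
      patient_id = character(), sex = factor(levels = .sex_levels),
      age_band = factor(levels = .age_levels), t2dm = logical(),
      raw_score = integer(),
      capped_band = factor(levels = .capped_levels), conditions = character()))
  }
  missing_demo <- setdiff(unique(claims$patient_id), demographics$patient_id)
  if (length(missing_demo)) {
    stop(sprintf("claims patient(s) missing from demographics: %s",
                 paste(head(missing_demo, 5L), collapse = ", ")), call. = FALSE)
  }
  sc <- if (nrow(claims)) .score_claims(claims, catalog, rule) else
    list(conditions = data.table::data.table(pid = character(), key = character()),
         t2dm_ids = character(), all_ids = character(),
         chronic_any_ids = character())

  keep <- switch(inclusion,
                 chronic_any = sc$chronic_any_ids,
                 any_dispensing = sc$all_ids,
                 all = demographics$patient_id)
  prof <- demographics[patient_id %in% keep]

  cond <- sc$conditions
  data.table::setorder(cond, pid, key)
  agg <- cond[, .(raw_score = .N, conditions = paste(key, collapse = ";")),
              by = pid]
  prof <- merge(prof, agg, by.x = "patient_id", by.y = "pid", all.x = TRUE)
  prof[is.na(raw_score), `:=`(raw_score = 0L, conditions = "")]
  prof[, t2dm := patient_id %in% sc$t2dm_ids]
  prof[, capped_band := factor(ifelse(raw_score >= 10L, ">=10",
                                      as.character(raw_score)),
                               levels = .capped_levels)]
  data.table::setorder(prof, patient_id)
  prof[, .(patient_id, sex, age_band, t2dm, raw_score, capped_band, conditions)]
}
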