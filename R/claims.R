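# Dispensing-claims data model: monthly records, demographics, study window.
# HSE-PCRS-style claims are collated monthly, so the calendar month is the
# native time resolution throughout.

.sex_levels <- c("female", "male")
.age_levels <- c("65-69", "70-74", ">=75")

# "YYYY-MM" <-> integer month index (year*12 + month-1); year boundaries are
# ordinary +1 steps, so 2009-12 is adjacent to 2010-01.
month_to_index <- function(month) {
  ok <- grepl("^[0-9]{4}-(0[1-9]|1[0-2])$", month)
  idx <- rep(NA_integer_, length(month))
  if (any(ok)) {
    y <- as.integer(substr(month[ok], 1, 4))
    m <- as.integer(substr(month[ok], 6, 7))
    idx[ok] <- y * 12L + (m - 1L)
  }
  idx
}

index_to_month <- function(idx) {
  sprintf("%04d-%02d", idx %/% 12L, idx %% 12L + 1L)
}

#' Define a study window
#'
#' The default spans the sixteen months 2009-11 through 2011-02: a calendar
#' year of interest padded by two months on each side so that three-month
#' chronic-dispensing runs straddling the year's edges are still observable.
#' Annual costs are summed over `cost_year` only.
#'
#' @param start_month,end_month inclusive bounds, `"YYYY-MM"`.
#' @param cost_year calendar year over which ingredient costs are summed.
#' @return a `study_window` object.
#' @examples
#' study_window()  # 2009-11 .. 2011-02, costs over 2010
#' @export
study_window <- function(start_month = "2009-11", end_month = "2011-02",
                         cost_year = 2010L) {
  s <- month_to_index(start_month)
  e <- month_to_index(end_month)
  if (is.na(s) || is.na(e) || e < s) {
    stop("invalid study window bounds", call. = FALSE)
  }
  structure(list(start_month = start_month, end_month = end_month,
                 start_idx = s, end_idx = e, cost_year = as.integer(cost_year)),
            class = "study_window")
}

#' @export
print.study_window <- function(x, ...) {
  cat(sprintf("<study_window %s..%s (%d months), cost year %d>\n",
              x$start_month, x$end_month, x$end_idx - x$start_idx + 1L,
              x$cost_year))
  invisible(x)
}

window_months <- function(window) index_to_month(window$start_idx:window$end_idx)

#' Longest run of consecutive calendar months
#'
#' The calendar substrate of the chronicity rule: a condition is considered
#' chronic only when its medication class was dispensed in at least three
#' consecutive months. Year boundaries are handled (`2009-12` is adjacent to
#' `2010-01`); duplicates are ignored.
#'
#' @param months character vector of `"YYYY-MM"` months (a set; order and
#'   multiplicity are irrelevant).
#' @return integer: length of the longest adjacent-month run, 0 for empty
#'   input.
#' @examples
#' month_run_length(c("2010-01", "2010-02", "2010-03"))  # 3
#' month_run_length(c("2009-12", "2010-01", "2010-03"))  # 2
#' @export
month_run_length <- function(months) {
  if (!length(months)) return(0L)
  idx <- month_to_index(months)
  if (anyNA(idx)) {
    stop(sprintf("unparseable month(s): %s",
                 paste(unique(months[is.na(idx)]), collapse = ", ")),
         call. = FALSE)
  }
  idx <- sort(unique(idx))
  if (length(idx) == 1L) return(1L)
  brk <- which(diff(idx) != 1L)
  max(diff(c(0L, brk, length(idx))))
}

#' Read dispensing claims
#'
#' Comma-delimited UTF-8 text with header
#' `patient_id,month,atc_code,ingredient_cost`. ATC codes are uppercased;
#' records outside the study window are dropped (with a message giving the
#' count); the result is ordered by patient, month, code.
#'
#' @param path claims CSV path.
#' @param window a [study_window()].
#' @param strict logical; if `TRUE` (default) malformed rows (bad month,
#'   invalid ATC code, negative/non-finite cost) abort with the offending
#'   line numbers, otherwise they are skipped with a message.
#' @return a `data.table` with columns `patient_id`, `month`, `atc_code`,
#'   `ingredient_cost`, and attributes `window` and `n_dropped_outside`.
#' @export
read_claims <- function(path, window = study_window(), strict = TRUE) {
  need <- c("patient_id", "month", "atc_code", "ingredient_cost")
  hdr <- names(data.table::fread(path, nrows = 0L))
  if (!all(need %in% hdr)) {
    stop(sprintf("claims file must have header %s", paste(need, collapse = ",")),
         call. = FALSE)
  }
  dt <- data.table::fread(path, colClasses = list(
    character = c("patient_id", "month", "atc_code"),
    numeric = "ingredient_cost"))
  dt <- dt[, need, with = FALSE]
  dt[, atc_code := toupper(atc_code)]
  midx <- month_to_index(dt$month)
  bad <- is.na(midx) | !atc_is_full(dt$atc_code) |
    !is.finite(dt$ingredient_cost) | dt$ingredient_cost < 0
  if (any(bad)) {
    lines <- which(bad) + 1L  # header is line 1
    msg <- sprintf("%d malformed claims row(s) at line(s): %s",
                   sum(bad), paste(head(lines, 10L), collapse = ", "))
    if (strict) stop(msg, call. = FALSE)
    message(msg, " (skipped)")
    dt <- dt[!bad]
    midx <- midx[!bad]
  }
  outside <- midx < window$start_idx | midx > window$end_idx
  n_drop <- sum(outside)
  if (n_drop) {
    message(sprintf("dropped %d record(s) outside window %s..%s", n_drop,
                    window$start_month, window$end_month))
    dt <- dt[!outside]
  }
  data.table::setorder(dt, patient_id, month, atc_code)
  data.table::setattr(dt, "window", window)
  data.table::setattr(dt, "n_dropped_outside", n_drop)
  dt[]
}

#' Write dispensing claims
#'
#' Emits the same dialect [read_claims()] consumes (comma-delimited, header,
#' `.` decimal, two-decimal costs).
#'
#' @param claims claims `data.table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_claims <- function(claims, path) {
  out <- data.table::as.data.table(claims)
  out <- out[, .(patient_id, month, atc_code,
                 ingredient_cost = sprintf("%.2f", ingredient_cost))]
  data.table::fwrite(out, path)
  invisible(path)
}

#' Read a demographics table
#'
#' Comma-delimited text with header `patient_id,sex,age_band`; `sex` must be
#' `male`/`female`, `age_band` one of `65-69`, `70-74`, `>=75` (the study
#' population is aged 65 and over). One row per patient.
#'
#' @param path demographics CSV path.
#' @return a `data.table` with factor columns `sex` and `age_band`.
#' @export
read_demographics <- function(path) {
  dt <- data.table::fread(path, colClasses = "character")
  need <- c("patient_id", "sex", "age_band")
  if (!all(need %in% names(dt))) {
    stop(sprintf("demographics file must have header %s",
                 paste(need, collapse = ",")), call. = FALSE)
  }
  dt <- dt[, need, with = FALSE]
  validate_demographics(dt)
}

validate_demographics <- function(dt) {
  dt <- data.table::as.data.table(dt)
  if (anyDuplicated(dt$patient_id)) {
    stop(sprintf("duplicate patient_id in demographics: %s",
                 dt$patient_id[duplicated(dt$patient_id)][1L]), call. = FALSE)
  }
  bad_sex <- setdiff(unique(dt$sex), .sex_levels)
  if (length(bad_sex)) {
    stop(sprintf("unknown sex value(s): %s", paste(bad_sex, collapse = ", ")),
         call. = FALSE)
  }
  bad_age <- setdiff(unique(dt$age_band), .age_levels)
  if (length(bad_age)) {
    stop(sprintf("unknown age_band value(s): %s (study population is >=65)",
                 paste(bad_age, collapse = ", ")), call. = FALSE)
  }
  dt[, sex := factor(sex, levels = .sex_levels)]
  dt[, age_band := factor(age_band, levels = .age_levels)]
  data.table::setorder(dt, patient_id)
  dt[]
}
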