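#' @keywords internal
"_PACKAGE"

#' @import data.table
#' @importFrom stats glm binomial coef quantile qnorm chisq.test median
#'   rbinom rgamma runif plogis qlogis setNames
#' @importFrom utils head
NULL

# WHO ATC grammar: anatomical-group letter, two digits (therapeutic subgroup),
# then optionally pharmacological-subgroup letter, chemical-subgroup letter,
# and a two-digit chemical-substance code. Truncation is only legal at
# component boundaries, so pattern lengths are 1, 3, 4, 5 or 7.
.atc_first_letters <- "ABCDGHJLMNPRSV"

.atc_pattern_regex <- sprintf(
  "^[%s]([0-9]{2}([A-Z]([A-Z]([0-9]{2})?)?)?)?$", .atc_first_letters)

#' Validate ATC code syntax
#'
#' Checks strings against the WHO Anatomical Therapeutic Chemical grammar:
#' a level-1 letter (one of `A B C D G H J L M N P R S V`), two digits, then
#' optionally one letter, one letter, and two digits. Truncations at component
#' boundaries are allowed when `allow_truncated = TRUE` (lengths 1, 3, 4, 5, 7);
#' otherwise only full 7-character codes pass.
#'
#' @param codes character vector of candidate codes.
#' @param allow_truncated logical; accept hierarchy-level truncations.
#' @return logical vector, `TRUE` where the code is syntactically valid.
#' @examples
#' atc_is_valid(c("C10AA05", "A10B", "X99ZZ99", "NO2AX05"))
#' atc_is_valid("A10B", allow_truncated = FALSE)
#' @export
atc_is_valid <- function(codes, allow_truncated = TRUE) {
  ok <- grepl(.atc_pattern_regex, codes)
  if (!allow_truncated) ok <- ok & nchar(codes) == 7L
  ok & !is.na(codes)
}

# Full dispensing-level code: 7 characters, complete grammar.
atc_is_full <- function(codes) atc_is_valid(codes, allow_truncated = FALSE)

assert_full_atc <- function(code, what = "code") {
  if (length(code) != 1L || !atc_is_full(code)) {
    stop(sprintf(
      "%s must be a single full 7-character ATC code (got %s); truncated queries are not allowed",
      what, deparse(code)), call. = FALSE)
  }
  invisible(code)
}

# Vectorised pattern match: pattern of length < 7 is a prefix pattern,
# length 7 is exact (equivalently: a 7-character prefix).
atc_pattern_matches <- function(patterns, code) {
  startsWith(code, patterns)
}
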