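# RxRiskV (mod) catalog: ATC pattern sets per chronic-condition category.

.norm_chr <- function(x) {
  x <- as.character(unlist(x, use.names = FALSE))
  x[!is.na(x) & nzchar(x)]
}

new_category <- function(name, includes, excludes = character(),
                         all_of_groups = list(), verbatim_literals = character(),
                         corrected_codes = character(), priority_rank,
                         concordant = FALSE) {
  structure(
    list(name = name,
         includes = .norm_chr(includes),
         excludes = .norm_chr(excludes),
         all_of_groups = lapply(all_of_groups, .norm_chr),
         verbatim_literals = .norm_chr(verbatim_literals),
         corrected_codes = .norm_chr(corrected_codes),
         priority_rank = as.integer(priority_rank),
         concordant = isTRUE(concordant)),
    class = "rx_category")
}

validate_category <- function(cat) {
  pats <- c(cat$includes, cat$excludes, cat$corrected_codes,
            unlist(cat$all_of_groups, use.names = FALSE))
  bad <- pats[!atc_is_valid(pats) | nchar(pats) < 3L | nchar(pats) == 6L]
  if (length(bad)) {
    stop(sprintf("category '%s': malformed ATC pattern(s): %s",
                 cat$name, paste(unique(bad), collapse = ", ")), call. = FALSE)
  }
  if (!length(cat$includes)) {
    stop(sprintf("category '%s': empty include list", cat$name), call. = FALSE)
  }
  invisible(cat)
}

#' Load an RxRiskV (mod) catalog
#'
#' Reads a catalog from a JSON file or by built-in identifier. The package
#' ships `"rxriskv_mod_2010"`, the 42-category modified RxRiskV mapping for
#' the Irish elderly claims setting (diabetes intentionally absent: treated
#' type 2 diabetes is the index condition, identified separately).
#'
#' The shipped catalog preserves three printed code literals that violate the
#' ATC grammar verbatim (they match nothing and are flagged by
#' [lint_catalog()]); when `corrected = TRUE` (default) the plausibly intended
#' codes are added as ordinary patterns.
#'
#' @param path path to a catalog JSON file, or a built-in identifier.
#' @param corrected logical; include corrected forms of non-conforming
#'   printed literals as matchable patterns.
#' @return an object of class `rx_catalog`: list with `version` and
#'   `categories` (each an `rx_category` with include/exclude pattern sets,
#'   optional all-of groups, a unique `priority_rank`, and a `concordant`
#'   flag).
#' @examples
#' cat42 <- load_catalog("rxriskv_mod_2010")
#' length(cat42$categories)
#' @export
load_catalog <- function(path = "rxriskv_mod_2010", corrected = TRUE) {
  if (!file.exists(path)) {
    builtin <- system.file("extdata", paste0(path, ".json"),
                           package = "rxcomorbid")
    if (!nzchar(builtin)) {
      stop(sprintf("catalog file or built-in id not found: '%s'", path),
           call. = FALSE)
    }
    path <- builtin
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(raw$categories) || !length(raw$categories)) {
    stop("catalog schema error: empty or missing category list", call. = FALSE)
  }
  cats <- lapply(raw$categories, function(x) {
    cat <- new_category(
      name = x$name,
      includes = x$includes,
      excludes = x$excludes,
      all_of_groups = if (is.null(x$all_of_groups)) list() else x$all_of_groups,
      verbatim_literals = x$verbatim_literals,
      corrected_codes = x$corrected_codes,
      priority_rank = x$priority_rank,
      concordant = x$concordant)
    validate_category(cat)
    if (corrected && length(cat$corrected_codes)) {
      cat$includes <- unique(c(cat$includes, cat$corrected_codes))
    }
    cat
  })
  nms <- vapply(cats, `[[`, "", "name")
  if (anyDuplicated(nms)) {
    stop(sprintf("catalog schema error: duplicate category name '%s'",
                 nms[duplicated(nms)][1L]), call. = FALSE)
  }
  ranks <- vapply(cats, `[[`, 0L, "priority_rank")
  if (anyDuplicated(ranks) || any(is.na(ranks)) || any(ranks < 1L)) {
    stop("catalog schema error: priority_rank values must be unique positive integers",
         call. = FALSE)
  }
  structure(list(version = if (is.null(raw$version)) "unversioned" else raw$version,
                 categories = cats[order(ranks)]),
            class = "rx_catalog")
}

#' Serialise a catalog to JSON
#'
#' Inverse of [load_catalog()] (with `corrected = FALSE` semantics: corrected
#' codes are written to their own field, not merged into the includes).
#'
#' @param catalog an `rx_catalog`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "rx_catalog"))
  cats <- lapply(catalog$categories, function(cat) {
    cat$includes <- setdiff(cat$includes, cat$corrected_codes)
    unclass(cat)
  })
  writeLines(jsonlite::toJSON(list(version = catalog$version, categories = cats),
                              auto_unbox = TRUE, pretty = TRUE), path)
  invisible(path)
}

#' @export
print.rx_catalog <- function(x, ...) {
  cat(sprintf("<rx_catalog '%s': %d categories>\n", x$version,
              length(x$categories)))
  invisible(x)
}

#' Fetch a catalog category by name
#' @param catalog an `rx_catalog`.
#' @param name category label.
#' @return the `rx_category`, or an error if absent.
#' @export
catalog_category <- function(catalog, name) {
  nms <- vapply(catalog$categories, `[[`, "", "name")
  i <- match(name, nms)
  if (is.na(i)) stop(sprintf("no category named '%s'", name), call. = FALSE)
  catalog$categories[[i]]
}

#' Match a full ATC code against one category
#'
#' A code matches when it falls under at least one include pattern and under
#' no exclude pattern; exclusion always dominates. Patterns shorter than 7
#' characters match by ATC-hierarchy prefix; 7-character patterns are exact.
#'
#' @param category an `rx_category` (see [catalog_category()] /
#'   [load_catalog()]).
#' @param code a single full 7-character ATC code. Truncated queries error:
#'   patterns may be truncated, queries may not.
#' @return `TRUE` or `FALSE`.
#' @examples
#' cat42 <- load_catalog()
#' match_code(catalog_category(cat42, "Hyperlipidemia"), "C10AA05")  # TRUE
#' match_code(catalog_category(cat42, "Allergies"), "R06AX27")      # FALSE
#' @export
match_code <- function(category, code) {
  stopifnot(inherits(category, "rx_category"))
  assert_full_atc(code, "query code")
  if (length(category$excludes) &&
      any(atc_pattern_matches(category$excludes, code))) {
    return(FALSE)
  }
  any(atc_pattern_matches(category$includes, code))
}

#' Categories matching a full ATC code, in priority order
#'
#' Returns every category whose include/exclude sets admit `code`, ordered by
#' ascending `priority_rank`. The first element is the single category the
#' code resolves to under multi-indication resolution (each medication is
#' credited to its highest-ranked indication only).
#'
#' @inheritParams match_code
#' @param catalog an `rx_catalog`.
#' @return character vector of category names (possibly empty).
#' @export
categories_for_code <- function(catalog, code) {
  stopifnot(inherits(catalog, "rx_catalog"))
  assert_full_atc(code, "query code")
  hit <- vapply(catalog$categories, match_code, NA, code = code)
  vapply(catalog$categories[hit], `[[`, "", "name")  # already rank-ordered
}

#' Lint a catalog
#'
#' Deterministic consistency report over a catalog:
#' * `ambiguous`: include patterns under which some full code would match
#'   more than one category (requires priority resolution) — detected by
#'   pairwise pattern prefix overlap.
#' * `orphan_excludes`: exclude patterns shadowed by no include pattern of
#'   the same category.
#' * `nonconforming`: literals that violate the ATC grammar (the shipped
#'   catalog carries the printed literals `NO2AX05`, `N0BC09`, `NO2BA01`
#'   verbatim; all are flagged here).
#'
#' @param catalog an `rx_catalog`.
#' @return list with data.frames `ambiguous`, `orphan_excludes`,
#'   `nonconforming`.
#' @export
lint_catalog <- function(catalog) {
  stopifnot(inherits(catalog, "rx_catalog"))
  cats <- catalog$categories
  nms <- vapply(cats, `[[`, "", "name")

  # pairwise overlap: patterns p, q overlap iff one is a prefix of the other
  amb <- list()
  for (i in seq_along(cats)) {
    for (j in seq_along(cats)) {
      if (j <= i) next
      for (p in cats[[i]]$includes) {
        hit <- startsWith(cats[[j]]$includes, p) | startsWith(p, cats[[j]]$includes)
        if (any(hit)) {
          amb[[length(amb) + 1L]] <- data.frame(
            pattern = p, category_a = nms[i], category_b = nms[j],
            overlapping = paste(cats[[j]]$includes[hit], collapse = ";"))
        }
      }
    }
  }
  amb <- if (length(amb)) do.call(rbind, amb) else
    data.frame(pattern = character(), category_a = character(),
               category_b = character(), overlapping = character())

  orph <- list()
  for (cat in cats) {
    for (e in cat$excludes) {
      shadowed <- any(startsWith(e, cat$includes) | startsWith(cat$includes, e))
      if (!shadowed) {
        orph[[length(orph) + 1L]] <- data.frame(category = cat$name, exclude = e)
      }
    }
  }
  orph <- if (length(orph)) do.call(rbind, orph) else
    data.frame(category = character(), exclude = character())

  noncon <- list()
  for (cat in cats) {
    lits <- c(cat$verbatim_literals,
              cat$includes[!atc_is_valid(cat$includes)],
              cat$excludes[!atc_is_valid(cat$excludes)])
    for (l in unique(lits)) {
      noncon[[length(noncon) + 1L]] <- data.frame(category = cat$name, literal = l)
    }
  }
  noncon <- if (length(noncon)) do.call(rbind, noncon) else
    data.frame(category = character(), literal = character())

  o <- order(noncon$category, noncon$literal)
  structure(list(ambiguous = amb, orphan_excludes = orph,
                 nonconforming = noncon[o, , drop = FALSE]),
            class = "rx_lint_report")
}

#' @export
print.rx_lint_report <- function(x, ...) {
  cat(sprintf("catalog lint: %d ambiguous pattern pair(s), %d orphan exclude(s), %d non-conforming literal(s)\n",
              nrow(x$ambiguous), nrow(x$orphan_excludes), nrow(x$nonconforming)))
  if (nrow(x$nonconforming)) {
    cat("non-conforming:",
        paste(sprintf("%s [%s]", x$nonconforming$literal, x$nonconforming$category),
              collapse = ", "), "\n")
  }
  invisible(x)
}
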