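# Brute-force oracles, deliberately independent of the package's vectorised
# implementation: plain loops, substr() comparisons, exhaustive run
# enumeration.

# standalone ATC grammar oracle (regular expression written independently)
oracle_atc_full <- function(code) {
  grepl("^[ABCDGHJLMNPRSV][0-9][0-9][A-Z][A-Z][0-9][0-9]$", code)
}

oracle_prefix <- function(pattern, code) {
  nchar(code) >= nchar(pattern) && substr(code, 1, nchar(pattern)) == pattern
}

oracle_match <- function(category, code) {
  for (e in category$excludes) if (oracle_prefix(e, code)) return(FALSE)
  for (p in category$includes) if (oracle_prefix(p, code)) return(TRUE)
  FALSE
}

oracle_categories <- function(catalog, code) {
  hits <- character()
  ranks <- integer()
  for (cat in catalog$categories) {
    if (oracle_match(cat, code)) {
      hits <- c(hits, cat$name)
      ranks <- c(ranks, cat$priority_rank)
    }
  }
  hits[order(ranks)]
}

# exhaustive longest-run check: is there any block of `len` consecutive
# months entirely inside `months`?
oracle_has_run <- function(months, len) {
  if (!length(months)) return(FALSE)
  idx <- sort(unique(sapply(months, function(m) {
    as.integer(substr(m, 1, 4)) * 12L + as.integer(substr(m, 6, 7)) - 1L
  })))
  for (s in idx) {
    if (all((s + seq_len(len) - 1L) %in% idx)) return(TRUE)
  }
  FALSE
}

oracle_run_length <- function(months) {
  best <- 0L
  len <- 1L
  while (oracle_has_run(months, len)) {
    best <- len
    len <- len + 1L
  }
  best
}

# brute-force condition assignment for one patient's claims (data.frame with
# month, atc_code): per-code highest-priority resolution, pooled months per
# category, exhaustive run check; all-of categories judged on raw matches.
oracle_assign <- function(claims, catalog, min_consecutive = 3L) {
  codes <- unique(toupper(claims$atc_code))
  res <- list()
  for (cd in codes) {
    hits <- oracle_categories(catalog, cd)
    if (length(hits)) res[[cd]] <- hits[[1L]]
  }
  assigned <- character()
  for (cat in catalog$categories) {
    if (length(cat$all_of_groups)) {
      ok <- TRUE
      for (grp in cat$all_of_groups) {
        months <- character()
        for (i in seq_len(nrow(claims))) {
          cd <- toupper(claims$atc_code[i])
          raw_hit <- FALSE
          for (p in grp) if (oracle_prefix(p, cd)) raw_hit <- TRUE
          for (e in cat$excludes) if (oracle_prefix(e, cd)) raw_hit <- FALSE
          if (raw_hit) months <- c(months, claims$month[i])
        }
        if (!oracle_has_run(months, min_consecutive)) ok <- FALSE
      }
      if (ok) assigned <- c(assigned, cat$name)
    } else {
      months <- character()
      for (i in seq_len(nrow(claims))) {
        cd <- toupper(claims$atc_code[i])
        if (!is.null(res[[cd]]) && res[[cd]] == cat$name) {
          months <- c(months, claims$month[i])
        }
      }
      if (oracle_has_run(months, min_consecutive)) {
        assigned <- c(assigned, cat$name)
      }
    }
  }
  sort(assigned)
}

oracle_t2dm <- function(claims, min_consecutive = 3L) {
  months <- claims$month[substr(toupper(claims$atc_code), 1, 4) == "A10B"]
  oracle_has_run(months, min_consecutive)
}

# textbook Pearson chi-square by explicit summation
oracle_chisq <- function(tab) {
  tot <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      e <- sum(tab[i, ]) * sum(tab[, j]) / tot
      stat <- stat + (tab[i, j] - e)^2 / e
    }
  }
  stat
}

# independent iteratively-reweighted least squares logistic fit
oracle_irls <- function(X, y, tol = 1e-10, maxit = 50L) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- as.vector(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    new <- solve(t(X) %*% (X * w), t(X) %*% (w * z))
    if (max(abs(new - beta)) < tol) {
      beta <- as.vector(new)
      break
    }
    beta <- as.vector(new)
  }
  beta
}
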