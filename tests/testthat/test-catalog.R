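catalog <- load_catalog()

test_that("shipped catalog has the 42 expected categories and no diabetes", {
  nms <- vapply(catalog$categories, `[[`, "", "name")
  expect_length(nms, 42L)
  expect_false(anyDuplicated(nms) > 0)
  expect_true(all(c("Hyperlipidemia", "Ostomy", "Chronic Heart failure",
                    "Pain - Opiates") %in% nms))
  expect_false(any(grepl("diabetes", nms, ignore.case = TRUE)))
  # index-disease drugs (A10*) must not be claimable by any category
  for (cat in catalog$categories) {
    expect_false(any(startsWith(cat$includes, "A10")), info = cat$name)
  }
  ranks <- vapply(catalog$categories, `[[`, 0L, "priority_rank")
  expect_identical(sort(ranks), 1:42)
  conc <- nms[vapply(catalog$categories, `[[`, NA, "concordant")]
  expect_setequal(conc, c("Hyperlipidemia", "Anti-platelet therapy",
                          "Heart disease", "Hypertension"))
})

test_that("catalog schema errors are raised", {
  expect_error(load_catalog(mini_catalog_json(list())), "empty")
  expect_error(
    load_catalog(mini_catalog_json(list(
      mini_cat("Bad", "X99ZZ99", priority_rank = 1L)))),
    "X99ZZ99")
  expect_error(
    load_catalog(mini_catalog_json(list(
      mini_cat("Dup", "C10AA", priority_rank = 1L),
      mini_cat("Dup", "C07AB", priority_rank = 2L)))),
    "duplicate")
  expect_error(
    load_catalog(mini_catalog_json(list(
      mini_cat("A", "C10AA", priority_rank = 1L),
      mini_cat("B", "C07AB", priority_rank = 1L)))),
    "priority_rank")
  # length-6 truncation violates the grammar
  expect_error(
    load_catalog(mini_catalog_json(list(
      mini_cat("Bad6", "C10AA0", priority_rank = 1L)))),
    "C10AA0")
})

test_that("match_code honours prefixes, exact codes and exclusion dominance", {
  hyper <- catalog_category(catalog, "Hyperlipidemia")
  expect_true(match_code(hyper, "C10AA05"))
  expect_false(match_code(hyper, "N02AA01"))
  allerg <- catalog_category(catalog, "Allergies")
  expect_false(match_code(allerg, "R06AX27"))
  expect_true(match_code(allerg, "R06AX02"))
  expect_error(match_code(hyper, "A10B"), "full 7-character")
  expect_error(match_code(hyper, "C10AA056"), "full 7-character")
})

test_that("categories_for_code resolves in priority order", {
  expect_identical(categories_for_code(catalog, "C03CA01"),
                   "Chronic Heart failure")
  expect_identical(categories_for_code(catalog, "V01AA01"), character())
  expect_error(categories_for_code(catalog, "A10B"), "full 7-character")
  # N05AN01 sits in both Bipolar disorder and Psychotic illness
  hits <- categories_for_code(catalog, "N05AN01")
  expect_identical(hits, c("Bipolar disorder", "Psychotic illness"))
})

test_that("match_code agrees with the brute-force oracle on random codes", {
  set.seed(202)
  letters1 <- strsplit("ABCDGHJLMNPRSV", "")[[1]]
  codes <- vapply(1:1000, function(i) {
    sprintf("%s%02d%s%s%02d", sample(letters1, 1), sample(0:99, 1),
            sample(LETTERS, 1), sample(LETTERS, 1), sample(0:99, 1))
  }, "")
  # bias half the sample toward prefixes that exist in the catalog
  stems <- unlist(lapply(catalog$categories, `[[`, "includes"))
  pad <- c("3" = "AA01", "4" = "A01", "5" = "01", "7" = "")
  codes[1:500] <- vapply(1:500, function(i) {
    s <- sample(stems, 1)
    paste0(s, pad[[as.character(nchar(s))]])
  }, "")
  codes <- codes[atc_is_valid(codes, allow_truncated = FALSE)]
  for (cat in catalog$categories) {
    got <- vapply(codes, match_code, NA, category = cat, USE.NAMES = FALSE)
    want <- vapply(codes, oracle_match, NA, category = cat, USE.NAMES = FALSE)
    expect_identical(got, want, info = cat$name)
  }
})

test_that("corrected literal switch works and lint flags verbatim forms", {
  opi <- catalog_category(catalog, "Pain - Opiates")
  expect_true(match_code(opi, "N02AX05"))
  raw <- load_catalog(corrected = FALSE)
  expect_false(match_code(catalog_category(raw, "Pain - Opiates"), "N02AX05"))

  rep <- lint_catalog(catalog)
  expect_true(all(c("NO2AX05", "N0BC09") %in% rep$nonconforming$literal))
  expect_identical(
    rep$nonconforming$category[rep$nonconforming$literal == "NO2AX05"],
    "Pain - Opiates")
  expect_identical(
    rep$nonconforming$category[rep$nonconforming$literal == "N0BC09"],
    "Parkinson's disease")
  expect_identical(lint_catalog(catalog), lint_catalog(catalog))  # deterministic
})

test_that("lint handles trivial and constructed-overlap catalogs", {
  one <- load_catalog(mini_catalog_json(list(
    mini_cat("Solo", "C10AA05", priority_rank = 1L))))
  rep1 <- lint_catalog(one)
  expect_identical(nrow(rep1$ambiguous) + nrow(rep1$orphan_excludes) +
                     nrow(rep1$nonconforming), 0L)

  two <- load_catalog(mini_catalog_json(list(
    mini_cat("First", "C03CA", priority_rank = 1L),
    mini_cat("Second", c("C03CA", "C07AB"), priority_rank = 2L))))
  rep2 <- lint_catalog(two)
  expect_true(any(rep2$ambiguous$pattern == "C03CA"))
  # orphan exclude: no include shares the stem
  orph <- load_catalog(mini_catalog_json(list(
    mini_cat("Odd", "C10AA", excludes = "N02AA01", priority_rank = 1L))))
  expect_identical(lint_catalog(orph)$orphan_excludes$exclude, "N02AA01")
})

test_that("catalog round-trips through serialisation", {
  tf <- tempfile(fileext = ".json")
  write_catalog(catalog, tf)
  expect_identical(load_catalog(tf), catalog)
  raw <- load_catalog(corrected = FALSE)
  tf2 <- tempfile(fileext = ".json")
  write_catalog(raw, tf2)
  expect_identical(load_catalog(tf2, corrected = FALSE), raw)
})
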