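test_that("prevalence marginals from counts reproduce hand arithmetic", {
  counts <- data.frame(
    sex = rep(c("male", "female"), each = 2),
    age_band = "65-69",
    group = rep(c("t2dm", "non_t2dm"), 2),
    n = c(10, 90, 5, 95))
  pv <- prevalence_from_counts(counts)
  expect_identical(pv$n_total, 200)
  expect_identical(pv$prevalence_overall_pct, 7.5)
  expect_identical(unname(pv$prevalence_by_sex_pct["male"]), 10.0)
  expect_identical(unname(pv$prevalence_by_sex_pct["female"]), 5.0)
  # zero-prevalence edge
  z <- prevalence_from_counts(data.frame(sex = "male", age_band = ">=75",
                                         group = "non_t2dm", n = 50))
  expect_identical(z$prevalence_overall_pct, 0)
  expect_error(prevalence_from_counts(data.frame(sex = "male",
                                                 age_band = ">=75",
                                                 group = "t2dm", n = 0)),
               "empty")
  expect_error(prevalence_table(make_profiles(integer(), logical())), "empty")
})

test_that("median/IQR uses attainable integer (type-1) quartiles", {
  p <- make_profiles(c(3, 5, 6), t2dm = TRUE)
  m <- median_iqr_table(p)
  pooled <- m[m$sex == "all" & m$group == "t2dm", ]
  expect_identical(unlist(pooled[, c("median_score", "q1", "q3")],
                          use.names = FALSE), c(5, 3, 6))
  single <- median_iqr_table(make_profiles(4L, TRUE))
  srow <- single[single$sex == "all" & single$group == "t2dm", ]
  expect_identical(unlist(srow[, c("median_score", "q1", "q3")],
                          use.names = FALSE), c(4, 4, 4))
  # empty strata present with n = 0, no error
  expect_identical(
    single[single$sex == "male" & single$age_band == ">=75" &
             single$group == "t2dm", ]$n, 0L)
})

test_that("high/low split: threshold, chi-square, null and degenerate cases", {
  # identical distributions in the two groups -> OR ~ 1, tiny chi-square
  scores <- rep(c(0, 2, 4, 6, 8), times = 40)
  p <- make_profiles(c(scores, scores), t2dm = rep(c(TRUE, FALSE), each = 200),
                     sex = rep(c("female", "male"), 200),
                     age_band = rep(c("65-69", "70-74", ">=75"), length.out = 400))
  hl <- high_low_split(p)
  expect_identical(hl$threshold, 4)
  expect_lt(abs(hl$adjusted_or$or - 1), 1e-6)
  expect_lt(hl$chi_square$statistic, 1e-8)
  expect_identical(hl$chi_square$df, 1L)

  # all scores at/above the threshold in both groups -> degenerate
  pd <- make_profiles(rep(5, 40), t2dm = rep(c(TRUE, FALSE), 20))
  hld <- high_low_split(pd)
  expect_true(hld$chi_square$degenerate)
  expect_true(is.na(hld$chi_square$statistic))
  expect_error(high_low_split(make_profiles(c(1, 2), FALSE)), "no T2DM")
})

test_that("distribution chi-square matches the textbook formula", {
  p <- make_profiles(rep(c(1, 1, 2, 2), 10),
                     t2dm = rep(c(TRUE, FALSE), 20))
  d <- distribution_chi_square(p)
  expect_identical(d$statistic, 0)
  expect_identical(d$df, 1L)

  # hand 2x3 table via profiles, checked against explicit summation
  scores <- c(rep(0, 12), rep(1, 30), rep(2, 18), rep(0, 20), rep(1, 25),
              rep(2, 15))
  grp <- rep(c(TRUE, FALSE), c(60, 60))
  p2 <- make_profiles(scores, grp)
  d2 <- distribution_chi_square(p2)
  tab <- table(scores, grp)
  expect_equal(d2$statistic, oracle_chisq(tab), tolerance = 1e-12)
  expect_identical(d2$df, 2L)
  # permutation invariance of the statistic
  expect_equal(d2$statistic,
               distribution_chi_square(p2[sample(nrow(p2)), ])$statistic,
               tolerance = 1e-12)
  expect_error(distribution_chi_square(make_profiles(c(1, 2), TRUE)),
               "non-empty")
})

test_that("adjusted ORs match an independent IRLS fit on a small fixture", {
  # 8-patient worked fixture, chosen so the likelihood has a finite maximum
  prof <- make_profiles(
    raw_score = c(0, 5, 4, 1, 3, 0, 2, 1),
    t2dm = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    age_band = c("65-69", "70-74", "65-69", "70-74", "65-69", "70-74",
                 "65-69", "70-74"),
    sex = c("female", "female", "male", "male", "female", "female",
            "male", "male"),
    conditions = c("", "Hyperlipidemia", "Hyperlipidemia", "",
                   "Hyperlipidemia", "", "", ""))
  res <- adjusted_odds_ratios(prof, min_prevalence_pct = 10)
  expect_identical(res$condition, "Hyperlipidemia")

  y <- as.integer(grepl("Hyperlipidemia", prof$conditions))
  X <- cbind(1, prof$t2dm, prof$age_band == "70-74", prof$sex == "male")
  beta <- oracle_irls(X, y)
  expect_equal(log(res$odds_ratio), beta[2], tolerance = 1e-6)

  # cross-product-ratio property: constant covariates reduce to the 2x2 OR
  set.seed(77)
  cond <- rbinom(200, 1, 0.4)
  t2 <- rbinom(200, 1, 0.3) == 1
  prof2 <- make_profiles(cond, t2,
                         conditions = ifelse(cond == 1, "Hyperlipidemia", ""))
  res2 <- adjusted_odds_ratios(prof2, min_prevalence_pct = 10)
  tab <- table(t2, cond)
  cpr <- (tab[2, 2] * tab[1, 1]) / (tab[2, 1] * tab[1, 2])
  expect_equal(res2$odds_ratio, cpr, tolerance = 1e-6)
})

test_that("null covariate-free condition has CI covering 1", {
  set.seed(88)
  n <- 4000
  cond <- rbinom(n, 1, 0.3)
  prof <- make_profiles(cond, rbinom(n, 1, 0.1) == 1,
                        sex = sample(c("female", "male"), n, TRUE),
                        age_band = sample(c("65-69", "70-74", ">=75"), n, TRUE),
                        conditions = ifelse(cond == 1, "Anxiety", ""))
  res <- adjusted_odds_ratios(prof, min_prevalence_pct = 10)
  expect_true(res$ci_low <= 1 && 1 <= res$ci_high)
  expect_false(res$separated)
})

test_that("prevalence filter and formatting contracts hold", {
  prof <- make_profiles(
    c(1, 1, 1, 0, 0, 0, 0, 0, 0, 1),
    t2dm = rep(c(TRUE, FALSE), 5),
    conditions = c("Gout", "Gout", "Gout;Anxiety", "", "", "", "", "", "",
                   "Anxiety"))
  res <- adjusted_odds_ratios(prof, min_prevalence_pct = 25)
  expect_identical(res$condition, "Gout")  # Anxiety at 20% < 25%
  expect_identical(round_half_up(c(0.15, 2.345, -0.15, 9.695),
                                 c(1, 2, 1, 1)[1]),
                   c(0.2, 2.3, -0.2, 9.7))
  expect_identical(round_half_up(1.735, 2), 1.74)
  expect_identical(format_p(c(0.00005, 0.0321, NA)),
                   c("<0.0001", "0.0321", NA))
})
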