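test_that("energy adjustment removes the energy component exactly", {
  set.seed(4)
  n <- 1000
  energy <- rlnorm(n, log(1800), 0.3)
  nut <- data.frame(energy = energy,
                    alcohol = rexp(n, 1 / 5),
                    prop = 0.1 * energy,                    # proportional
                    indep = rnorm(n, 50, 5),                # uncorrelated
                    folate = 200 + 0.15 * energy + rnorm(n, 0, 30))
  rownames(nut) <- sprintf("s%04d", 1:n)
  adj <- energy_adjust(nut)
  # proportional nutrient collapses to its value at mean energy
  expect_lt(diff(range(adj$prop)), 1e-8)
  expect_equal(adj$prop[1], 0.1 * mean(energy))
  # uncorrelated nutrient unchanged up to an additive constant
  shift <- adj$indep - nut$indep
  expect_lt(sd(shift), 0.05 * sd(nut$indep))
  # residual orthogonality
  for (v in c("prop", "indep", "folate"))
    expect_lt(abs(cov(adj[[v]], energy)) /
                (sd(nut$folate) * sd(energy)), 1e-10)
  # alcohol and energy untouched
  expect_identical(adj$alcohol, nut$alcohol)
  expect_identical(adj$energy, nut$energy)
  expect_setequal(attr(adj, "energy_adjusted"), c("prop", "indep", "folate"))
})

test_that("energy adjustment guards degenerate inputs", {
  nut <- data.frame(energy = rep(2000, 5), folate = rnorm(5, 400))
  expect_error(energy_adjust(nut), "zero variance")
  expect_error(energy_adjust(data.frame(folate = 1:5)), "energy")
})

test_that("alcohol categorization matches the published cut points", {
  res <- categorize_alcohol(c(0, 0.05, 4.9, 5, 14.9, 15, 29.95, 30, 31))
  expect_equal(as.character(res$binary),
               c("nondrinker", rep("drinker", 8)))
  expect_equal(as.character(res$five_level),
               c("nondrinker", "0.1-4.9 g/day", "0.1-4.9 g/day",
                 "5.0-14.9 g/day", "5.0-14.9 g/day", "15-29.9 g/day",
                 "15-29.9 g/day", ">30 g/day", ">30 g/day"))
  expect_error(categorize_alcohol(-1), "negative")
})

test_that("smoking strata partition subjects with the right covariates", {
  g <- matrix(rbinom(36, 2, 0.3), 12, 3,
              dimnames = list(NULL, paste0("rs", 1:3)))
  smoking <- rep(c("never", "former", "current"), each = 4)
  ds <- make_dataset(g, rep(0:1, 6), smoking = smoking)
  ds$phenotype$cessation_age[5:8] <- c(39, 40, 53, 54)
  ds$phenotype$pack_years[9:12] <- c(26, 27, 54, 83)
  strata <- stratify_smoking(ds)
  ids <- lapply(strata, function(s) s$phenotype$subject_id)
  expect_equal(sort(unname(unlist(ids))), sort(ds$phenotype$subject_id))
  expect_equal(sum(lengths(ids)), 12L)
  never_f <- attr(strata$never, "forced")
  expect_setequal(colnames(never_f), c("sex", "age", "family_history", "ets"))
  former_f <- attr(strata$former, "forced")
  expect_true(any(grepl("40-53", colnames(former_f))))
  expect_false(any(grepl("pack", colnames(former_f))))
  # boundary categories
  expect_equal(as.character(cessation_age_category(c(39, 40, 53, 54))),
               c("<40", "40-53", "40-53", ">=54"))
  expect_equal(as.character(pack_year_category(c(26, 27, 54, 83))),
               c("<27", "27-53", "54-82", ">=83"))
  # former smoker with missing cessation age is dropped with a warning
  ds$phenotype$cessation_age[5] <- NA
  expect_warning(s2 <- stratify_smoking(ds), "former")
  expect_equal(nrow(s2$former$phenotype), 3L)
})

test_that("descriptive summary reproduces published-scale 2x2 statistics", {
  # gender split: 854/838 in cases vs 579/660 in controls -> Yates p 0.049
  status <- rep(c(1, 0), c(1692, 1239))
  sex <- c(rep(c("male", "female"), c(854, 838)),
           rep(c("male", "female"), c(579, 660)))
  g <- matrix(rbinom(2931 * 1, 2, 0.3), ncol = 1,
              dimnames = list(NULL, "rs1"))
  ds <- make_dataset(g, status)
  ds$phenotype$sex <- sex
  summ <- descriptive_summary(ds, variables = list(
    sex = list(kind = "categorical", values = sex)))
  expect_equal(round(summ$p_value[1], 3), 0.049)
  expect_match(summ$cases[summ$level == "male"], "50.5")
  # identical arms give chi-square p = 1
  sex_bal <- rep(c("male", "female"), length.out = 2931)
  summ2 <- descriptive_summary(ds, variables = list(
    sex = list(kind = "categorical", values = sex_bal)))
  expect_equal(summ2$p_value[1], 1)
})

test_that("Table-1-shaped counts reproduce printed percentages within 0.1", {
  smoking_cases <- rep(c("never", "former", "current"), c(466, 645, 581))
  smoking_controls <- rep(c("never", "former", "current"), c(510, 326, 403))
  status <- rep(c(1, 0), c(1692, 1239))
  ds <- make_dataset(matrix(rbinom(2931, 2, .3), ncol = 1,
                            dimnames = list(NULL, "rs1")), status)
  summ <- descriptive_summary(ds, variables = list(
    smoking = list(kind = "categorical",
                   values = c(smoking_cases, smoking_controls))))
  pct <- as.numeric(sub(".*\\(([0-9.]+)\\)", "\\1", summ$controls))
  printed <- c(32.5, 26.3, 41.1)[match(summ$level,
                                       c("current", "former", "never"))]
  expect_true(all(abs(pct - printed) <= 0.1 + 1e-8))
})

test_that("crude categorical odds ratios use the Woolf interval", {
  counts <- matrix(c(116, 147, 86, 228), 2,
                   dimnames = list(c("non", "drinkers"),
                                   c("cases", "controls")))
  or <- categorical_odds_ratios(counts, "non")
  expect_equal(round(or$or[or$level == "drinkers"], 2), 0.48)
  expect_lt(or$lower[2], 0.48); expect_gt(or$upper[2], 0.48)
  # equal counts -> OR 1; direct arithmetic on a (10,20;20,10) table
  counts2 <- matrix(c(10, 20, 20, 10), 2,
                    dimnames = list(c("x", "ref"), c("cases", "controls")))
  expect_equal(categorical_odds_ratios(counts2, "ref")$or[1], 0.25)
  counts3 <- matrix(c(5, 5, 7, 7), 2,
                    dimnames = list(c("ref", "x"), c("cases", "controls")))
  expect_equal(categorical_odds_ratios(counts3, "ref")$or[2], 1)
  counts2[1, 1] <- 0
  expect_error(categorical_odds_ratios(counts2, "ref"), "continuity")
})
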