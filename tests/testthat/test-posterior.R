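fake_chains <- function(gammas, betas = NULL, scale = NULL) {
  # build a minimal ssvs_chains-shaped object from draw matrices
  m <- ncol(gammas[[1]])
  ids <- colnames(gammas[[1]])
  if (is.null(ids)) ids <- paste0("v", seq_len(m))
  chains <- lapply(seq_along(gammas), function(i) {
    g <- gammas[[i]]; colnames(g) <- ids
    b <- if (is.null(betas)) matrix(0, nrow(g), m + 1) else betas[[i]]
    colnames(b) <- c("intercept", ids)
    list(beta = b, gamma = g)
  })
  design <- list(ids = ids, X_forced = matrix(1, 1, 1,
                                              dimnames = list(NULL, "intercept")),
                 scale = if (is.null(scale)) setNames(rep(1, m), ids)
                         else scale)
  prior <- assemble_prior(ids, "intercept")
  structure(list(chains = chains, design = design, prior = prior,
                 config = sampler_config(n_iter = 10, n_chains = length(gammas))),
            class = "ssvs_chains")
}

test_that("PPIs are draw fractions and pool by draw-count weighting", {
  g1 <- cbind(v1 = rep(c(1, 0), c(600, 400)))
  g2 <- cbind(v1 = rep(c(1, 0), c(100, 400)))
  ch <- fake_chains(list(g1, g2))
  expect_equal(unname(compute_ppi(ch)), (600 + 100) / 1500)
  per <- compute_ppi(ch, pooled = FALSE)
  w <- c(1000, 500)
  expect_equal(unname(compute_ppi(ch)), sum(per[, 1] * w) / sum(w))
  expect_equal(unname(compute_ppi(fake_chains(list(cbind(v1 = rep(1, 50)))))),
               1)
})

test_that("Bayes factors are posterior odds over prior odds", {
  expect_equal(bayes_factor(0.5, 0.5), 1)
  expect_equal(bayes_factor(0.75, 0.5), 3)
  expect_equal(bayes_factor(0.9, 0.5), 9)
  expect_identical(bayes_factor(1, 0.5), Inf)
  expect_error(bayes_factor(0.5, 1), "strictly")
  # strictly increasing in ppi; BF(p) = 1
  ppis <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(bayes_factor(ppis, 0.3)) > 0))
  expect_equal(bayes_factor(0.3, 0.3), 1)
})

test_that("expected FDR is the mean miss probability of the selected set", {
  expect_equal(expected_fdr(1), 0)
  expect_equal(expected_fdr(c(0.90, 0.88)), 0.11)
  expect_equal(expected_fdr(c(0.99, 0.98, 0.83, 0.82, 0.80, 0.78, 0.75)),
               0.15)
  expect_true(is.na(expected_fdr(numeric(0))))
  # properties on random sets
  set.seed(15)
  for (i in 1:20) {
    p <- runif(sample(2:8, 1))
    e <- expected_fdr(p)
    expect_equal(e, expected_fdr(rev(p)))
    expect_gte(e, 1 - max(p)); expect_lte(e, 1 - min(p))
    extra <- runif(1, 0, min(p))
    expect_gte(expected_fdr(c(p, extra)), e)   # adding weaker never helps
  }
})

test_that("conditional odds ratios use inclusion draws only", {
  g <- cbind(v1 = rep(c(1, 0), c(400, 600)))
  b <- cbind(0, v1 = c(rep(0.7, 400), rnorm(600, 5)))
  ch <- fake_chains(list(g), list(b))
  res <- conditional_odds_ratio(ch, "v1")
  expect_equal(res$or, exp(0.7))
  expect_equal(res$lower, exp(0.7)); expect_equal(res$upper, exp(0.7))
  expect_false(res$unstable)
  # symmetric draws about zero -> OR near 1
  set.seed(5)
  g2 <- cbind(v1 = rep(1, 4000))
  b2 <- cbind(0, v1 = rnorm(4000, 0, 0.3))
  res2 <- conditional_odds_ratio(fake_chains(list(g2), list(b2)), "v1")
  expect_equal(res2$or, 1, tolerance = 2 * 0.3 / sqrt(4000) * 3)
  # rescaling by a column sd divides the log-OR exactly
  ch3 <- fake_chains(list(g), list(b), scale = c(v1 = 2))
  res3 <- conditional_odds_ratio(ch3, "v1", unit_scaling = "per_unit")
  expect_equal(log(res3$or), 0.7 / 2)
  # too few inclusion draws flags unstable
  g4 <- cbind(v1 = rep(c(1, 0), c(5, 995)))
  res4 <- conditional_odds_ratio(fake_chains(list(g4), list(b)), "v1")
  expect_true(res4$unstable)
})

test_that("convergence check pools on correlation with a constant fallback", {
  a <- c(0.9, 0.1, 0.5, 0.7); b <- a + c(0.01, -0.01, 0.02, 0)
  expect_true(convergence_check(rbind(a, b))$pooled)
  expect_equal(convergence_check(rbind(a, a))$correlation, 1)
  expect_false(convergence_check(rbind(a, rev(a)))$pooled)
  # constant vector: fall back to max |diff|
  cst <- rep(0.2, 4)
  expect_true(convergence_check(rbind(cst, cst + 0.01))$pooled)
  expect_false(convergence_check(rbind(cst, cst + 0.2))$pooled)
})

test_that("selection thresholds are strict as published", {
  summ <- data.frame(variable = c("a", "b", "c"),
                     ppi = c(0.36, 0.35, 0.20),
                     bf = c(3.10, 2.22, 0.5))
  expect_equal(as.character(select_variables(summ, ppi_threshold = 0.35)),
               "a")
  expect_equal(as.character(select_variables(summ, bf_threshold = 3)), "a")
  expect_length(select_variables(summ[0, ], ppi_threshold = 0.35), 0)
  expect_error(select_variables(summ), "exactly one")
  # with p = 0.5, BF > 3 is the same rule as PPI > 0.75
  set.seed(33)
  ppis <- runif(200)
  bfs <- bayes_factor(ppis, 0.5)
  expect_identical(bfs > 3, ppis > 0.75)
})

test_that("posterior_summary assembles the final-model table", {
  set.seed(77)
  n <- 300
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("v1", "v2")))
  y <- rbinom(n, 1, plogis(1.2 * X[, 1]))
  des <- stratum_design(y, NULL, X, standardize = FALSE)
  pri <- assemble_prior(c("v1", "v2"), "intercept")
  ch <- run_ssvs(des, pri, quick_config(8000, seed = 21))
  summ <- posterior_summary(ch, gene_map = c(v1 = "MTRR", v2 = "TYMS"))
  expect_s3_class(summ, "posterior_summary")
  expect_equal(summ$gene, c("MTRR", "TYMS"))
  expect_true(summ$selected[1])
  expect_gt(summ$or[1], 1)
  expect_true(all(summ$ci_lower <= summ$ci_upper, na.rm = TRUE))
  expect_equal(attr(summ, "efdr"),
               expected_fdr(summ$ppi[summ$selected]))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_posterior_summary(summ, path)
  expect_true(any(grepl("expected_fdr", readLines(path))))
})
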