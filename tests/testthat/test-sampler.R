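make_toy_design <- function(n = 40, m = 3, seed = 5, standardize = FALSE) {
  set.seed(seed)
  X <- matrix(rnorm(n * m), n, m,
              dimnames = list(NULL, paste0("v", seq_len(m))))
  y <- rbinom(n, 1, plogis(0.8 * X[, 1]))
  stratum_design(y, NULL, X, standardize = standardize)
}

test_that("log posterior decomposes into its stated terms", {
  des <- make_toy_design()
  pri <- assemble_prior(paste0("v", 1:3), "intercept")
  m <- 3
  # all-zero coefficients: likelihood is -n log 2
  lp0 <- log_posterior(0, rep(0, m), rep(0, m), des, pri)
  ll0 <- -length(des$response) * log(2)
  # gamma all-1 vs all-0 at beta = 0 differ by m * log(1/c)
  lp1 <- log_posterior(0, rep(0, m), rep(1, m), des, pri)
  expect_equal(lp1 - lp0, m * log(1 / pri$c))
  # full value matches an independent sum-of-terms recomputation
  set.seed(31)
  bf <- rnorm(1); bs <- rnorm(m, 0, 0.3); gam <- c(1, 0, 1)
  eta <- bf + drop(des$X_sel %*% bs)
  ll <- sum(dbinom(des$response, 1, plogis(eta), log = TRUE))
  d <- pri$tau * ifelse(gam == 1, pri$c, 1)
  lprior <- sum(dnorm(bs, 0, d, log = TRUE)) +
    dnorm(bf, 0, pri$sigma_forced, log = TRUE) + m * log(0.5)
  expect_equal(log_posterior(bf, bs, gam, des, pri), ll + lprior,
               tolerance = 1e-10)
  expect_equal(lp0 - ll0,
               sum(dnorm(rep(0, m), 0, pri$tau, log = TRUE)) +
                 dnorm(0, 0, pri$sigma_forced, log = TRUE) + m * log(0.5))
})

test_that("inclusion updates follow the spike/slab density ratio", {
  pri <- assemble_prior(paste0("v", 1:3), tau = 0.05, c = 10, p = 0.5)
  # beta_j = 0: ratio f1/f0 = 1/c -> P = 1/(1+c)
  set.seed(1)
  up <- update_inclusion(c(0, 0, 0), c(0, 0, 0), 1, pri)
  expect_equal(up$prob, 1 / 11, tolerance = 1e-12)
  # beta_j far in the slab: inclusion nearly certain
  up2 <- update_inclusion(c(0.5, 0, 0), c(0, 0, 0), 1, pri)
  expect_gt(up2$prob, 0.999)
  # p_j = 1 forces inclusion
  pri3 <- assemble_prior("v1", p = 1)
  expect_equal(update_inclusion(0, 0, 1, pri3)$gamma_j, 1)
})

test_that("the augmented full conditional solves the stated linear system", {
  des <- make_toy_design(n = 25)
  pri <- assemble_prior(paste0("v", 1:3), "intercept")
  set.seed(12)
  omega <- rgamma(25, 2, 8)
  gam <- c(1, 0, 1)
  fc <- beta_full_conditional(omega, des, pri, gam)
  X <- cbind(des$X_forced, des$X_sel)
  kappa <- des$response - 0.5
  expect_equal(drop(fc$precision %*% fc$mean), drop(crossprod(X, kappa)),
               tolerance = 1e-8)
  # precision = X'Omega X + blockdiag(1/sigma_f^2, D^-1 R^-1 D^-1)
  d <- pri$tau * ifelse(gam == 1, pri$c, 1)
  Pref <- crossprod(X, X * omega)
  Pref[1, 1] <- Pref[1, 1] + 1 / pri$sigma_forced^2
  Pref[2:4, 2:4] <- Pref[2:4, 2:4] + diag(1 / d) %*% pri$Rinv %*% diag(1 / d)
  expect_equal(fc$precision, Pref, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("chains are deterministic given the seed and sized by burn-in", {
  des <- make_toy_design()
  pri <- assemble_prior(paste0("v", 1:3), "intercept")
  cfg <- sampler_config(n_iter = 3000, n_chains = 2, seed = 99)
  ch1 <- run_ssvs(des, pri, cfg)
  ch2 <- run_ssvs(des, pri, cfg)
  expect_identical(ch1$chains[[1]]$beta, ch2$chains[[1]]$beta)
  expect_identical(ch1$chains[[2]]$gamma, ch2$chains[[2]]$gamma)
  expect_equal(nrow(ch1$chains[[1]]$beta), 2000L)  # last two thirds kept
  cfg2 <- sampler_config(n_iter = 300, n_chains = 1, seed = 1, thin = 2)
  ch3 <- run_ssvs(des, pri, cfg2)
  expect_equal(nrow(ch3$chains[[1]]$beta), 100L)
})

test_that("PG draws match Polya-Gamma moments", {
  set.seed(6)
  for (z in c(0, 1, 3)) {
    x <- rpg(100000, z)
    m_th <- if (z == 0) 0.25 else tanh(z / 2) / (2 * z)
    expect_equal(mean(x), m_th, tolerance = 0.01)
    expect_true(all(x > 0))
  }
})

test_that("posterior PPIs agree with the enumeration oracle", {
  set.seed(42)
  n <- 60
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("v1", "v2", "v3")))
  y <- rbinom(n, 1, plogis(-0.2 + 0.9 * X[, 1]))
  des <- stratum_design(y, NULL, X, standardize = FALSE)
  pri <- assemble_prior(c("v1", "v2", "v3"), "intercept")
  oracle <- enumerate_inclusion_probs(des, pri)
  ch <- run_ssvs(des, pri, sampler_config(20000, 2, seed = 3))
  expect_lt(max(abs(compute_ppi(ch) - oracle$ppi)), 0.03)
})

test_that("permuting variables permutes the PPIs", {
  set.seed(14)
  n <- 80
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("v1", "v2", "v3")))
  y <- rbinom(n, 1, plogis(0.7 * X[, 1] - 0.4 * X[, 3]))
  A <- matrix(c(1, .4, .1, .4, 1, .2, .1, .2, 1), 3)
  perm <- c(3, 1, 2)
  mk <- function(cols, R) {
    dimnames(R) <- list(colnames(X)[cols], colnames(X)[cols])
    des <- stratum_design(y, NULL, X[, cols], standardize = FALSE)
    pri <- assemble_prior(colnames(X)[cols], "intercept", R = R)
    compute_ppi(run_ssvs(des, pri, sampler_config(20000, 2, seed = 4)))
  }
  ppi_a <- mk(1:3, A)
  ppi_b <- mk(perm, A[perm, perm])
  expect_lt(max(abs(ppi_a[colnames(X)[perm]] - ppi_b)), 0.02)
})

test_that("the RW-MH fallback adapts into a healthy acceptance window", {
  des <- make_toy_design(n = 120, m = 4, seed = 9, standardize = TRUE)
  pri <- assemble_prior(paste0("v", 1:4), "intercept")
  cfg <- sampler_config(n_iter = 4000, n_chains = 1, seed = 2,
                        algorithm = "rwmh")
  ch <- run_ssvs(des, pri, cfg)
  acc <- ch$chains[[1]]$accept_rate
  expect_true(all(acc > 0.1 & acc < 0.6))
  # both algorithms target the same posterior
  chpg <- run_ssvs(des, pri, sampler_config(20000, 1, seed = 2))
  chmh <- run_ssvs(des, pri, sampler_config(20000, 1, seed = 3,
                                            algorithm = "rwmh"))
  expect_lt(max(abs(compute_ppi(chpg) - compute_ppi(chmh))), 0.08)
})
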