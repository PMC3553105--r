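#' Stratum design matrix for the SSVS sampler
#'
#' Assembles the per-stratum numeric design: the binary response, the
#' forced-in covariate matrix (an intercept column is prepended), and the
#' selectable-variable matrix. Continuous selectable columns (nutrients,
#' interactions) are standardized to mean 0, sd 1 inside the design so one
#' slab scale is sensible across units; SNP columns stay on the 0/1/2 scale
#' so their odds ratios read per minor allele. Centers and scales are
#' recorded for back-transformation of reported odds ratios.
#'
#' @param response binary vector (case = 1).
#' @param X_forced numeric matrix of forced covariates (no intercept; one is
#'   added as the first column).
#' @param X_sel numeric matrix of selectable variables, column names = ids.
#' @param snp_cols logical vector (or character ids) marking which selectable
#'   columns are SNP additive codes (left unstandardized).
#' @param standardize standardize non-SNP columns (default `TRUE`).
#' @param allow_constant keep constant selectable columns instead of erroring
#'   (only useful for prior-sampling checks).
#' @return object of class `stratum_design`.
#' @export
stratum_design <- function(response, X_forced, X_sel, snp_cols = NULL,
                           standardize = TRUE, allow_constant = FALSE) {
  response <- as.numeric(response)
  stopifnot(all(response %in% c(0, 1)))
  X_forced <- as.matrix(cbind(intercept = rep(1, length(response)),
                              X_forced))
  X_sel <- as.matrix(X_sel)
  if (is.null(colnames(X_sel)))
    colnames(X_sel) <- paste0("v", seq_len(ncol(X_sel)))
  if (anyNA(X_forced) || anyNA(X_sel)) stop("design contains missing values")
  if (nrow(X_forced) != length(response) || nrow(X_sel) != length(response))
    stop("design rows do not match the response length")
  if (is.character(snp_cols)) snp_cols <- colnames(X_sel) %in% snp_cols
  if (is.null(snp_cols)) snp_cols <- rep(FALSE, ncol(X_sel))
  sds <- apply(X_sel, 2L, stats::sd)
  if (!allow_constant && any(sds == 0))
    stop("constant selectable column(s): ",
         paste(colnames(X_sel)[sds == 0], collapse = ", "))
  center <- rep(0, ncol(X_sel))
  scale <- rep(1, ncol(X_sel))
  if (standardize && ncol(X_sel)) {
    std <- !snp_cols & sds > 0
    center[std] <- colMeans(X_sel[, std, drop = FALSE])
    scale[std] <- sds[std]
    X_sel[, std] <- sweep(sweep(X_sel[, std, drop = FALSE], 2L, center[std]),
                          2L, scale[std], "/")
  }
  structure(list(response = response, X_forced = X_forced, X_sel = X_sel,
                 ids = colnames(X_sel), snp_cols = snp_cols,
                 center = stats::setNames(center, colnames(X_sel)),
                 scale = stats::setNames(scale, colnames(X_sel))),
            class = "stratum_design")
}

#' MCMC configuration for the SSVS sampler
#'
#' @param n_iter iterations per chain (default 300000; a 20000-iteration
#'   profile is adequate for the bundled validation scenarios).
#' @param n_chains number of chains with distinct starting points (default 2).
#' @param burn_fraction fraction of each chain discarded (default 1/3, i.e.
#'   the last two thirds are kept).
#' @param thin thinning interval (default 1).
#' @param seed RNG seed for the whole run.
#' @param algorithm `"pg"` (Polya-Gamma augmented Gibbs; exact conditionals,
#'   no tuning) or `"rwmh"` (adaptive random-walk Metropolis fallback).
#' @return object of class `sampler_config`.
#' @export
sampler_config <- function(n_iter = 300000, n_chains = 2,
                           burn_fraction = 1 / 3, thin = 1, seed = 1,
                           algorithm = c("pg", "rwmh")) {
  stopifnot(n_iter > 0, n_chains >= 1, burn_fraction >= 0, burn_fraction < 1,
            thin >= 1)
  structure(list(n_iter = as.integer(n_iter), n_chains = as.integer(n_chains),
                 burn_fraction = burn_fraction, thin = as.integer(thin),
                 seed = as.integer(seed), algorithm = match.arg(algorithm)),
            class = "sampler_config")
}

#' Log posterior density of the SSVS logistic model
#'
#' Bernoulli-logit log likelihood plus the N(0, Sigma_gamma) log prior on the
#' selectable coefficients, the vague normal log prior on the forced
#' coefficients, and the Bernoulli log prior on the inclusion indicators.
#'
#' @param beta_forced,beta_sel coefficient vectors (forced incl. intercept).
#' @param gamma binary inclusion vector.
#' @param design a [stratum_design()].
#' @param prior a [assemble_prior()] spec.
#' @return the log posterior (unnormalized by the marginal likelihood only).
#' @export
log_posterior <- function(beta_forced, beta_sel, gamma, design, prior) {
  stopifnot(length(beta_forced) == ncol(design$X_forced),
            length(beta_sel) == ncol(design$X_sel),
            length(gamma) == length(beta_sel))
  eta <- drop(design$X_forced %*% beta_forced)
  if (length(beta_sel)) eta <- eta + drop(design$X_sel %*% beta_sel)
  loglik <- sum(design$response * eta - log1pexp(eta))
  Sg <- spike_slab_cov(gamma, prior)
  lp_sel <- ldmvnorm(beta_sel, Sg)
  lp_forced <- sum(stats::dnorm(beta_forced, 0, prior$sigma_forced,
                                log = TRUE))
  p <- prior$p
  lp_gamma <- sum(ifelse(gamma == 1, log(p), log(1 - p)))
  loglik + lp_sel + lp_forced + lp_gamma
}

# overflow-safe log(1 + exp(x))
log1pexp <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

# multivariate normal log density at x, mean 0
ldmvnorm <- function(x, Sigma) {
  if (!length(x)) return(0)
  L <- chol(Sigma)
  z <- backsolve(L, x, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(z^2)
}

#' Gibbs update of one inclusion indicator
#'
#' The full conditional P(gamma_j = 1 | beta_sel, gamma_-j) =
#' p_j f1 / (p_j f1 + (1 - p_j) f0), where f1 and f0 are the
#' N(beta_sel; 0, Sigma_gamma) densities with gamma_j set to 1 and 0.
#'
#' @param beta_sel selectable coefficient vector.
#' @param gamma current inclusion vector.
#' @param j index updated.
#' @param prior a [assemble_prior()] spec.
#' @return list with `prob` (conditional inclusion probability) and `gamma_j`
#'   (the Bernoulli draw, using the current RNG stream).
#' @export
update_inclusion <- function(beta_sel, gamma, j, prior) {
  g1 <- g0 <- gamma
  g1[j] <- 1; g0[j] <- 0
  pj <- prior$p[j]
  if (pj >= 1) return(list(prob = 1, gamma_j = 1))
  lf1 <- ldmvnorm(beta_sel, spike_slab_cov(g1, prior))
  lf0 <- ldmvnorm(beta_sel, spike_slab_cov(g0, prior))
  logit <- log(pj / (1 - pj)) + lf1 - lf0
  prob <- stats::plogis(logit)
  list(prob = prob, gamma_j = as.integer(stats::runif(1) < prob))
}

#' Gaussian full conditional of the coefficients under augmentation
#'
#' Given Polya-Gamma variables omega, beta | omega, gamma, y is multivariate
#' normal with precision X' Omega X + prior precision and mean solving
#' (X' Omega X + prior precision) m = X' kappa, kappa = y - 1/2. Returned for
#' verification and reuse; the C++ chain performs the same computation.
#'
#' @param omega Polya-Gamma auxiliary vector (one per subject).
#' @param design a [stratum_design()].
#' @param prior a [assemble_prior()] spec.
#' @param gamma current inclusion vector.
#' @return list with `mean` and `precision`.
#' @export
beta_full_conditional <- function(omega, design, prior, gamma) {
  X <- cbind(design$X_forced, design$X_sel)
  f <- ncol(design$X_forced)
  m <- ncol(design$X_sel)
  P <- matrix(0, f + m, f + m)
  diag(P)[seq_len(f)] <- 1 / prior$sigma_forced^2
  if (m) {
    dinv <- 1 / (prior$tau * ifelse(gamma == 1, prior$c, 1))
    P[f + seq_len(m), f + seq_len(m)] <- prior$Rinv * tcrossprod(dinv)
  }
  prec <- crossprod(X, X * omega) + P
  kappa <- design$response - 0.5
  list(mean = drop(solve(prec, crossprod(X, kappa))), precision = prec)
}

#' Run the spike-and-slab stochastic search sampler
#'
#' Samples (beta, gamma) from the SSVS posterior for logistic regression.
#' Chain 1 starts from the null model (gamma all zero); further chains start
#' from independent Bernoulli(p) draws of gamma. All beta start at zero.
#' The default algorithm is Polya-Gamma augmented Gibbs (exact conditionals);
#' `"rwmh"` is an adaptive random-walk Metropolis fallback targeting the same
#' posterior. Results are bit-reproducible given `config$seed`.
#'
#' @param design a [stratum_design()].
#' @param prior a [assemble_prior()] spec; ids must match `design$ids`.
#' @param config a [sampler_config()].
#' @return object of class `ssvs_chains`: list of per-chain results, each
#'   with matrices `beta` (kept draws x coefficients) and `gamma` (kept draws
#'   x selectable), plus the design, prior and config.
#' @export
run_ssvs <- function(design, prior, config = sampler_config()) {
  stopifnot(inherits(design, "stratum_design"),
            inherits(prior, "prior_spec"),
            inherits(config, "sampler_config"))
  if (!identical(design$ids, prior$selectable_ids))
    stop("design selectable ids do not match the prior spec")
  m <- ncol(design$X_sel)
  f <- ncol(design$X_forced)
  n_burn <- floor(config$n_iter * config$burn_fraction)
  set.seed(config$seed)
  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    gamma0 <- if (ch == 1) rep(0, m)
              else as.numeric(stats::runif(m) < prior$p)
    beta0 <- rep(0, f + m)
    res <- if (config$algorithm == "pg") {
      ssvs_chain_pg(design$response, design$X_forced, design$X_sel,
                    prior$Rinv, prior$tau, prior$c, prior$p,
                    prior$sigma_forced, config$n_iter, n_burn, config$thin,
                    gamma0, beta0)
    } else {
      ssvs_chain_rwmh(design, prior, config, gamma0, beta0, n_burn)
    }
    colnames(res$beta) <- c(colnames(design$X_forced), design$ids)
    colnames(res$gamma) <- design$ids
    if (any(!is.finite(res$beta)))
      stop("chain ", ch, " diverged: non-finite coefficient draw")
    chains[[ch]] <- res
  }
  structure(list(chains = chains, design = design, prior = prior,
                 config = config),
            class = "ssvs_chains")
}

#' @export
print.ssvs_chains <- function(x, ...) {
  cat("<ssvs_chains> ", length(x$chains), " chain(s) x ",
      nrow(x$chains[[1]]$gamma), " kept draws; ",
      length(x$design$ids), " selectable variables; algorithm ",
      x$config$algorithm, "\n", sep = "")
  invisible(x)
}

# Adaptive component-wise random-walk Metropolis fallback. Proposal log-sds
# adapt toward a 0.44 acceptance rate during burn-in only.
ssvs_chain_rwmh <- function(design, prior, config, gamma, beta, n_burn) {
  f <- ncol(design$X_forced)
  m <- ncol(design$X_sel)
  d <- f + m
  X <- cbind(design$X_forced, design$X_sel)
  y <- design$response
  ls <- rep(log(0.2), d)
  acc <- att <- rep(0, d)
  eta <- drop(X %*% beta)
  loglik_eta <- function(e) sum(y * e - log1pexp(e))
  ll <- loglik_eta(eta)
  lprior_beta <- function(b) {
    ldmvnorm(b[f + seq_len(m)], spike_slab_cov(gamma, prior)) +
      sum(stats::dnorm(b[seq_len(f)], 0, prior$sigma_forced, log = TRUE))
  }
  lp <- lprior_beta(beta)
  n_keep <- (config$n_iter - n_burn) %/% config$thin
  beta_draws <- matrix(NA_real_, n_keep, d)
  gamma_draws <- matrix(NA_integer_, n_keep, m)
  keep <- 0L
  for (it in seq_len(config$n_iter)) {
    for (k in seq_len(d)) {
      prop <- beta
      prop[k] <- beta[k] + exp(ls[k]) * stats::rnorm(1)
      eta_prop <- eta + X[, k] * (prop[k] - beta[k])
      ll_prop <- loglik_eta(eta_prop)
      lp_prop <- lprior_beta(prop)
      att[k] <- att[k] + 1
      if (log(stats::runif(1)) < ll_prop + lp_prop - ll - lp) {
        beta <- prop; eta <- eta_prop; ll <- ll_prop; lp <- lp_prop
        acc[k] <- acc[k] + 1
      }
      if (it <= n_burn && att[k] %% 50 == 0) {
        rate <- acc[k] / att[k]
        ls[k] <- ls[k] + (rate - 0.44) / sqrt(it / 50)
      }
    }
    if (m) {
      beta_sel <- beta[f + seq_len(m)]
      for (j in sample.int(m)) {
        gamma[j] <- update_inclusion(beta_sel, gamma, j, prior)$gamma_j
      }
      lp <- lprior_beta(beta)
    }
    if (it > n_burn && (it - n_burn) %% config$thin == 0 && keep < n_keep) {
      keep <- keep + 1L
      beta_draws[keep, ] <- beta
      gamma_draws[keep, ] <- gamma
    }
  }
  list(beta = beta_draws, gamma = gamma_draws,
       accept_rate = ifelse(att > 0, acc / att, NA_real_))
}
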