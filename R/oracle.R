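#' Exact posterior inclusion probabilities by model enumeration
#'
#' Independent validation route for small problems: enumerates all 2^m
#' inclusion patterns and computes each model's marginal likelihood by
#' adaptive Gauss-Hermite quadrature over the full coefficient vector
#' (forced + selectable), centered and scaled at the per-model posterior
#' mode and curvature. Posterior inclusion probabilities follow by summing
#' normalized model probabilities. Practical for m <= ~6 selectable
#' variables and a handful of forced covariates; it shares no code path with
#' the MCMC sampler.
#'
#' @param design a [stratum_design()].
#' @param prior a [assemble_prior()] spec.
#' @param nodes Gauss-Hermite nodes per dimension (default 11).
#' @return list with `ppi` (named vector), `log_model_prob` (per inclusion
#'   pattern) and the `patterns` matrix.
#' @export
enumerate_inclusion_probs <- function(design, prior, nodes = 11) {
  m <- length(design$ids)
  if (m > 12) stop("enumeration over 2^", m, " models is not practical")
  f <- ncol(design$X_forced)
  d <- f + m
  X <- cbind(design$X_forced, design$X_sel)
  y <- design$response
  gh <- gauss_hermite(nodes)
  grid <- as.matrix(expand.grid(rep(list(seq_len(nodes)), d)))
  zg <- matrix(gh$nodes[grid], nrow(grid), d)
  logw <- rowSums(matrix(log(gh$weights)[grid], nrow(grid), d))
  z2 <- rowSums(zg^2)

  patterns <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  colnames(patterns) <- design$ids
  logpost <- numeric(nrow(patterns))
  for (g in seq_len(nrow(patterns))) {
    gamma <- patterns[g, ]
    P <- matrix(0, d, d)
    diag(P)[seq_len(f)] <- 1 / prior$sigma_forced^2
    dinv <- 1 / (prior$tau * ifelse(gamma == 1, prior$c, 1))
    P[f + seq_len(m), f + seq_len(m)] <- prior$Rinv * tcrossprod(dinv)
    cholP <- chol(P)
    logdetP <- 2 * sum(log(diag(cholP)))
    h_many <- function(B) {  # rows of B are beta vectors
      eta <- B %*% t(X)
      drop(eta %*% y) - rowSums(log1pexp(eta)) -
        0.5 * (d * log(2 * pi) - logdetP) -
        0.5 * rowSums((B %*% t(cholP))^2)
    }
    neg_h <- function(b) -h_many(matrix(b, 1))
    grad_neg_h <- function(b) {
      eta <- drop(X %*% b)
      -(crossprod(X, y - stats::plogis(eta)) - P %*% b)
    }
    opt <- stats::optim(rep(0, d), neg_h, grad_neg_h, method = "BFGS")
    mode <- opt$par
    w <- stats::plogis(drop(X %*% mode))
    H <- crossprod(X, X * (w * (1 - w))) + P
    Cu <- chol(solve(H))        # covariance = t(Cu) %*% Cu
    pts <- matrix(mode, nrow(zg), d, byrow = TRUE) +
      sqrt(2) * zg %*% Cu
    log_integral <- 0.5 * d * log(2) - sum(log(diag(chol(H)))) +
      logsumexp(logw + z2 + h_many(pts))
    logpost[g] <- sum(ifelse(gamma == 1, log(prior$p), log(1 - prior$p))) +
      log_integral
  }
  prob <- exp(logpost - logsumexp(logpost))
  ppi <- drop(prob %*% patterns)
  names(ppi) <- design$ids
  list(ppi = ppi, log_model_prob = logpost - logsumexp(logpost),
       patterns = patterns)
}

logsumexp <- function(x) {
  mx <- max(x)
  mx + log(sum(exp(x - mx)))
}

# Gauss-Hermite nodes/weights (weight function exp(-x^2)) via Golub-Welsch
gauss_hermite <- function(k) {
  if (k == 1) return(list(nodes = 0, weights = sqrt(pi)))
  off <- sqrt(seq_len(k - 1) / 2)
  J <- matrix(0, k, k)
  J[cbind(seq_len(k - 1), seq_len(k - 1) + 1)] <- off
  J[cbind(seq_len(k - 1) + 1, seq_len(k - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * e$vectors[1, ord]^2)
}
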