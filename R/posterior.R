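#' Posterior inclusion probabilities
#'
#' Fraction of kept draws in which each inclusion indicator equals 1. With
#' `pooled = TRUE` (the default) draws from all chains are pooled; the pooled
#' PPI equals the draw-count-weighted mean of the per-chain PPIs.
#'
#' @param chains an `ssvs_chains` object from [run_ssvs()], or a list of
#'   chain results with `gamma` matrices.
#' @param pooled pool chains before averaging (default `TRUE`); otherwise a
#'   matrix of per-chain PPIs is returned.
#' @return named numeric vector of PPIs (or a chains x variables matrix).
#' @export
compute_ppi <- function(chains, pooled = TRUE) {
  ch <- if (inherits(chains, "ssvs_chains")) chains$chains else chains
  per <- do.call(rbind, lapply(ch, function(x) colMeans(x$gamma)))
  if (!pooled) return(per)
  w <- vapply(ch, function(x) nrow(x$gamma), numeric(1))
  drop(w %*% per) / sum(w)
}

#' Marginal Bayes factor from a posterior inclusion probability
#'
#' Posterior odds of inclusion divided by prior odds:
#' BF = \[ppi / (1 - ppi)\] / \[p / (1 - p)\]. A PPI of 1 returns `Inf`.
#'
#' @param ppi posterior inclusion probability (vectorized).
#' @param prior_p prior inclusion probability, strictly inside (0, 1).
#' @return the Bayes factor(s).
#' @export
bayes_factor <- function(ppi, prior_p = 0.5) {
  if (any(prior_p <= 0 | prior_p >= 1))
    stop("prior_p must lie strictly in (0, 1)")
  stopifnot(all(ppi >= 0 & ppi <= 1))
  post_odds <- ifelse(ppi == 1, Inf, ppi / (1 - ppi))
  post_odds / (prior_p / (1 - prior_p))
}

#' Expected false discovery rate of a selected set
#'
#' The model-averaged expected proportion of false selections: the mean of
#' (1 - PPI) over the selected variables.
#'
#' @param ppis PPIs of the selected set.
#' @return the expected FDR, or `NA` for an empty set.
#' @export
expected_fdr <- function(ppis) {
  if (!length(ppis)) return(NA_real_)
  mean(1 - ppis)
}

#' Conditional model-averaged odds ratio with credible interval
#'
#' OR = exp(posterior mean of the coefficient over draws in which the
#' variable is included); the 95% credible interval exponentiates the
#' 2.5th/97.5th percentiles of those draws. When the design standardized the
#' column, the log odds ratio can be rescaled back to the per-unit scale
#' (divide by the column's sd); the default reports per-sd.
#'
#' @param chains an `ssvs_chains` object.
#' @param j variable id (or index into the selectable variables).
#' @param ci credible level (default 0.95).
#' @param unit_scaling `"per_sd"` (default; coefficient as sampled) or
#'   `"per_unit"` (rescaled by the recorded column scale).
#' @param min_draws minimum inclusion draws before an estimate is reported
#'   (default 20; fewer gives `unstable = TRUE` and `NA` estimates).
#' @return list with `or`, `lower`, `upper`, `n_draws`, `unstable`.
#' @export
conditional_odds_ratio <- function(chains, j, ci = 0.95,
                                   unit_scaling = c("per_sd", "per_unit"),
                                   min_draws = 20L) {
  stopifnot(inherits(chains, "ssvs_chains"))
  unit_scaling <- match.arg(unit_scaling)
  ids <- chains$design$ids
  if (is.character(j)) j <- match(j, ids)
  beta <- do.call(rbind, lapply(chains$chains, function(x) x$beta))
  gamma <- do.call(rbind, lapply(chains$chains, function(x) x$gamma))
  f <- ncol(chains$design$X_forced)
  inc <- gamma[, j] == 1
  n_draws <- sum(inc)
  if (n_draws == 0)
    return(list(or = NA_real_, lower = NA_real_, upper = NA_real_,
                n_draws = 0L, unstable = TRUE))
  b <- beta[inc, f + j]
  if (unit_scaling == "per_unit") b <- b / chains$design$scale[j]
  qs <- stats::quantile(b, c((1 - ci) / 2, 1 - (1 - ci) / 2), names = FALSE)
  list(or = exp(mean(b)), lower = exp(qs[1]), upper = exp(qs[2]),
       n_draws = n_draws, unstable = n_draws < min_draws)
}

#' Chain agreement and pooling decision
#'
#' Pearson correlation of per-chain PPI vectors; chains are pooled when every
#' pairwise correlation reaches `min_corr`. If a PPI vector is constant the
#' correlation is undefined and the decision falls back to requiring a
#' maximum absolute PPI difference below 0.05.
#'
#' @param chains an `ssvs_chains` object (or per-chain PPI matrix).
#' @param min_corr pooling threshold (default 0.95).
#' @return list with `correlation` (minimum pairwise; `NA` if undefined),
#'   `max_diff`, and logical `pooled`.
#' @export
convergence_check <- function(chains, min_corr = 0.95) {
  per <- if (is.matrix(chains)) chains else compute_ppi(chains, pooled = FALSE)
  if (nrow(per) < 2L) stop("need at least 2 chains")
  cors <- c(); diffs <- c()
  for (a in seq_len(nrow(per) - 1L)) for (b in seq(a + 1L, nrow(per))) {
    diffs <- c(diffs, max(abs(per[a, ] - per[b, ])))
    if (stats::sd(per[a, ]) == 0 || stats::sd(per[b, ]) == 0)
      cors <- c(cors, NA_real_)
    else cors <- c(cors, stats::cor(per[a, ], per[b, ]))
  }
  pooled <- if (anyNA(cors)) max(diffs) < 0.05 else all(cors >= min_corr)
  list(correlation = if (anyNA(cors)) NA_real_ else min(cors),
       max_diff = max(diffs), pooled = pooled)
}

#' Select variables by PPI or Bayes-factor threshold
#'
#' Strict inequality, matching the screening rule "PPI greater than 0.35"
#' and the final-model rule "marginal Bayes factor greater than 3".
#'
#' @param summary a `posterior_summary` data.frame (or any data.frame with
#'   columns `variable`, `ppi`, `bf`).
#' @param ppi_threshold,bf_threshold exactly one must be supplied.
#' @return character vector of selected variable ids; the threshold kind and
#'   value are recorded in attributes.
#' @export
select_variables <- function(summary, ppi_threshold = NULL,
                             bf_threshold = NULL) {
  if (is.null(ppi_threshold) == is.null(bf_threshold))
    stop("supply exactly one of ppi_threshold, bf_threshold")
  if (!nrow(summary)) return(character(0))
  if (!is.null(ppi_threshold)) {
    out <- summary$variable[summary$ppi > ppi_threshold]
    attr(out, "threshold") <- c(kind = "ppi", value = ppi_threshold)
  } else {
    out <- summary$variable[summary$bf > bf_threshold]
    attr(out, "threshold") <- c(kind = "bf", value = bf_threshold)
  }
  out
}

#' Posterior summary table (per-variable inference)
#'
#' PPI, marginal Bayes factor, conditional model-averaged OR with credible
#' interval, and a selected flag per selectable variable, plus the expected
#' FDR of the selected set and the chain-agreement correlation.
#'
#' @param chains an `ssvs_chains` object.
#' @param gene_map optional named vector mapping variable id to gene label.
#' @param ppi_threshold,bf_threshold selection rule forwarded to
#'   [select_variables()] (default BF > 3).
#' @param unit_scaling forwarded to [conditional_odds_ratio()].
#' @return data.frame of class `posterior_summary` with attributes `efdr`,
#'   `convergence`, `selection_rule`.
#' @export
posterior_summary <- function(chains, gene_map = NULL, ppi_threshold = NULL,
                              bf_threshold = if (is.null(ppi_threshold)) 3,
                              unit_scaling = "per_sd") {
  stopifnot(inherits(chains, "ssvs_chains"))
  ids <- chains$design$ids
  ppi <- compute_ppi(chains)
  bf <- bayes_factor(ppi, mean(chains$prior$p))
  ors <- lapply(seq_along(ids), function(j)
    conditional_odds_ratio(chains, j, unit_scaling = unit_scaling))
  out <- data.frame(
    variable = ids,
    gene = if (is.null(gene_map)) NA_character_
           else unname(gene_map[ids]),
    or = vapply(ors, `[[`, numeric(1), "or"),
    ci_lower = vapply(ors, `[[`, numeric(1), "lower"),
    ci_upper = vapply(ors, `[[`, numeric(1), "upper"),
    ppi = unname(ppi), bf = unname(bf),
    n_inclusion_draws = vapply(ors, `[[`, numeric(1), "n_draws"),
    unstable = vapply(ors, `[[`, logical(1), "unstable"),
    stringsAsFactors = FALSE)
  sel <- select_variables(out, ppi_threshold = ppi_threshold,
                          bf_threshold = bf_threshold)
  out$selected <- out$variable %in% sel
  conv <- if (length(chains$chains) >= 2L) convergence_check(chains)
          else list(correlation = NA_real_, max_diff = NA_real_,
                    pooled = TRUE)
  structure(out, efdr = expected_fdr(out$ppi[out$selected]),
            convergence = conv,
            selection_rule = attr(sel, "threshold"),
            class = c("posterior_summary", "data.frame"))
}

#' Write a posterior summary as TSV
#'
#' Columns mirror a final-model report (variable, gene, OR, CI, PPI, Bayes
#' factor, selected) with an expected-FDR footer comment line.
#'
#' @param summary a [posterior_summary()].
#' @param path output TSV file.
#' @export
write_posterior_summary <- function(summary, path) {
  utils::write.table(as.data.frame(summary), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cat(sprintf("# expected_fdr_selected\t%.3f\n",
              attr(summary, "efdr")), file = path, append = TRUE)
  invisible(path)
}
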