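#' Prior correlation matrix with LD structure for SNPs
#'
#' Builds the prior correlation matrix R over the selectable variables. SNP
#' pairs on the same chromosome within `max_distance` base pairs take their
#' externally supplied r-squared (unsigned, as r-squared carries no sign);
#' SNP pairs farther apart or on different chromosomes are treated as
#' independent (entry 0). Nutrient and interaction rows/columns are identity
#' (independent normal priors centered at zero). The result is repaired to
#' the nearest positive-definite matrix by flooring eigenvalues at `eig_floor`
#' and rescaling to unit diagonal.
#'
#' @param variable_ids ordered ids of the selectable variables.
#' @param annotation SNP annotation (rsid, chrom, pos); variables whose id
#'   matches an annotated rsid are treated as SNPs, all others as
#'   nutrients/interactions.
#' @param r2 external r-squared source: a long data.frame (snp1, snp2, r2) as
#'   from [read_ld_tsv()], or a square [pairwise_r2()] matrix.
#' @param max_distance independence distance in base pairs (default 400000:
#'   SNPs farther apart are assumed independent).
#' @param eig_floor eigenvalue floor for the positive-definite repair.
#' @return correlation matrix over `variable_ids` (unit diagonal, symmetric,
#'   positive definite).
#' @export
build_prior_correlation <- function(variable_ids, annotation, r2,
                                    max_distance = 400000,
                                    eig_floor = 1e-6) {
  m <- length(variable_ids)
  R <- diag(m)
  dimnames(R) <- list(variable_ids, variable_ids)
  snp_ids <- intersect(variable_ids, annotation$rsid)
  if (length(snp_ids) >= 2L) {
    lookup <- r2_lookup(r2)
    ann <- annotation[match(snp_ids, annotation$rsid), ]
    for (a in seq_len(length(snp_ids) - 1L)) {
      for (b in seq(a + 1L, length(snp_ids))) {
        if (ann$chrom[a] != ann$chrom[b]) next
        if (abs(ann$pos[a] - ann$pos[b]) > max_distance) next
        val <- lookup(snp_ids[a], snp_ids[b])
        if (is.na(val)) {
          warning("SNP pair ", snp_ids[a], "/", snp_ids[b],
                  " absent from the external r2 table; using 0")
          val <- 0
        }
        R[snp_ids[a], snp_ids[b]] <- R[snp_ids[b], snp_ids[a]] <- val
      }
    }
  }
  repair_correlation(R, eig_floor)
}

r2_lookup <- function(r2) {
  if (is.matrix(r2)) {
    function(a, b) {
      if (!a %in% rownames(r2) || !b %in% colnames(r2)) return(NA_real_)
      r2[a, b]
    }
  } else {
    stopifnot(all(c("snp1", "snp2", "r2") %in% names(r2)))
    key <- c(paste(r2$snp1, r2$snp2), paste(r2$snp2, r2$snp1))
    val <- c(r2$r2, r2$r2)
    function(a, b) {
      i <- match(paste(a, b), key)
      if (is.na(i)) NA_real_ else val[i]
    }
  }
}

#' Repair a symmetric matrix to a positive-definite correlation matrix
#'
#' Floors eigenvalues at `eig_floor`, reconstructs, and rescales to unit
#' diagonal.
#'
#' @param R symmetric matrix with unit diagonal (approximately).
#' @param eig_floor minimum eigenvalue after repair.
#' @return positive-definite correlation matrix.
#' @export
repair_correlation <- function(R, eig_floor = 1e-6) {
  R <- (R + t(R)) / 2
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= eig_floor) return(R)
  v <- pmax(e$values, eig_floor)
  R2 <- e$vectors %*% (v * t(e$vectors))
  R2 <- stats::cov2cor(R2)
  dimnames(R2) <- dimnames(R)
  (R2 + t(R2)) / 2
}

#' Assemble a spike-and-slab prior specification
#'
#' The coefficient prior for the selectable variables is the structured
#' spike-and-slab N(0, D_gamma R D_gamma) with D_gamma diagonal: entry
#' `c * tau` when the variable is included (slab) and `tau` when excluded
#' (spike). Inclusion indicators have independent Bernoulli(`p`) priors.
#' Forced-in covariates (and the intercept) get independent vague
#' N(0, `sigma_forced`^2) priors and never enter selection.
#'
#' @param selectable_ids ordered ids of selectable variables.
#' @param forced_ids ids of forced-in covariates (disjoint from selectable).
#' @param R prior correlation matrix over selectable variables (default
#'   identity); must be positive definite (repair beforehand with
#'   [repair_correlation()]).
#' @param tau spike standard deviation (default 0.05: an excluded variable's
#'   log-odds-ratio is effectively zero).
#' @param c slab multiplier (> 1; default 10, i.e. slab sd 0.5 admitting
#'   per-unit odds ratios of roughly 0.4-2.7 at one prior sd).
#' @param p prior inclusion probability, scalar or per-variable, in (0, 1\]
#'   (default 0.5).
#' @param sigma_forced prior sd of forced coefficients (default 10).
#' @return object of class `prior_spec`.
#' @export
assemble_prior <- function(selectable_ids, forced_ids = character(0),
                           R = NULL, tau = 0.05, c = 10, p = 0.5,
                           sigma_forced = 10) {
  m <- length(selectable_ids)
  if (length(intersect(selectable_ids, forced_ids)))
    stop("ids listed both selectable and forced: ",
         paste(intersect(selectable_ids, forced_ids), collapse = ", "))
  if (anyDuplicated(c(selectable_ids, forced_ids)))
    stop("duplicated variable ids")
  if (tau <= 0) stop("tau must be positive")
  if (c <= 1) stop("slab multiplier c must exceed 1")
  p <- rep_len(p, m)
  if (any(p <= 0 | p > 1)) stop("inclusion probabilities must lie in (0, 1]")
  if (is.null(R)) R <- diag(m)
  R <- as.matrix(R)
  if (!isTRUE(all.equal(dim(R), c(m, m))))
    stop("R dimension does not match the number of selectable variables")
  if (max(abs(diag(R) - 1)) > 1e-8) stop("R must have unit diagonal")
  if (max(abs(R - t(R))) > 1e-8) stop("R must be symmetric")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("R is not positive definite; repair it with repair_correlation()")
  dimnames(R) <- list(selectable_ids, selectable_ids)
  structure(list(selectable_ids = selectable_ids, forced_ids = forced_ids,
                 R = R, Rinv = chol2inv(chol(R)), tau = tau, c = c,
                 p = p, sigma_forced = sigma_forced),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("<prior_spec> ", length(x$selectable_ids), " selectable + ",
      length(x$forced_ids), " forced; tau=", x$tau, " c=", x$c,
      " p=", paste(unique(x$p), collapse = ","),
      " sigma_forced=", x$sigma_forced, "\n", sep = "")
  invisible(x)
}

#' Spike-and-slab conditional prior covariance
#'
#' Sigma_gamma = D_gamma R D_gamma, where the diagonal D_gamma has entry
#' `c * tau` for included variables and `tau` for excluded ones.
#'
#' @param gamma binary inclusion vector over the selectable variables.
#' @param prior a [assemble_prior()] spec.
#' @return the covariance matrix.
#' @export
spike_slab_cov <- function(gamma, prior) {
  stopifnot(inherits(prior, "prior_spec"))
  m <- length(prior$selectable_ids)
  if (length(gamma) != m)
    stop("gamma length ", length(gamma), " != ", m, " selectable variables")
  d <- prior$tau * ifelse(gamma == 1, prior$c, 1)
  S <- prior$R * tcrossprod(d)
  dimnames(S) <- dimnames(prior$R)
  S
}
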