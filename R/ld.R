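#' Pairwise linkage-disequilibrium r-squared
#'
#' Squared Pearson correlation of additive genotype codes (composite LD),
#' computed on pairwise-complete observations. Monomorphic columns, and pairs
#' with fewer than two complete observations, yield `NA` entries with a
#' warning. The diagonal is 1 for polymorphic SNPs.
#'
#' @param genotypes numeric 0/1/2 matrix (subjects x SNPs) or an encoded
#'   [cohort_dataset()].
#' @return an `ld_matrix`: symmetric matrix of r-squared values in \[0, 1\]
#'   with attribute `source = "empirical"`.
#' @export
pairwise_r2 <- function(genotypes) {
  g <- if (inherits(genotypes, "cohort_dataset")) genotypes$genotypes
       else genotypes
  stopifnot(is.numeric(g))
  sds <- apply(g, 2L, stats::sd, na.rm = TRUE)
  mono <- is.na(sds) | sds == 0
  r <- suppressWarnings(stats::cor(g, use = "pairwise.complete.obs"))
  r2 <- r^2
  if (any(mono)) {
    warning("monomorphic or empty SNP column(s): ",
            paste(colnames(g)[mono], collapse = ", "))
    r2[mono, ] <- NA_real_
    r2[, mono] <- NA_real_
  }
  diag(r2)[!mono] <- 1
  # fewer than 2 complete pairs -> cor() already returns NA; keep but warn
  n_pair <- crossprod(!is.na(g))
  low <- n_pair < 2 & upper.tri(n_pair)
  if (any(low)) warning(sum(low), " SNP pair(s) with <2 complete observations")
  structure(r2, source = "empirical", class = c("ld_matrix", "matrix"))
}

#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' Exact test by default: the p-value sums the conditional probabilities,
#' given observed allele counts, of all heterozygote counts no more probable
#' than the observed one (computed by a numerically stable recurrence over
#' the heterozygote count). A Pearson chi-square variant against the p^2,
#' 2pq, q^2 expectation is also available. Monomorphic samples return p = 1.
#' In case-control QC this is conventionally evaluated on controls only (see
#' [hwe_test_dataset()]).
#'
#' @param n0,n1,n2 counts of reference-homozygote, heterozygote and
#'   alternate-homozygote genotypes.
#' @param method `"exact"` or `"chisq"`.
#' @return the p-value.
#' @export
hwe_test <- function(n0, n1, n2, method = c("exact", "chisq")) {
  method <- match.arg(method)
  stopifnot(n0 >= 0, n1 >= 0, n2 >= 0, n0 + n1 + n2 >= 1)
  n <- n0 + n1 + n2
  n_minor <- 2 * min(n0, n2) + n1   # rarer allele count
  if (n_minor == 0) return(1)
  if (method == "chisq") {
    p <- (2 * n0 + n1) / (2 * n)
    expd <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    if (any(expd == 0)) return(1)
    stat <- sum((c(n0, n1, n2) - expd)^2 / expd)
    return(stats::pchisq(stat, df = 1, lower.tail = FALSE))
  }
  # exact: distribution of heterozygote count given allele counts
  het_obs <- n1
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  # log P(n_het) up to a constant, via lchoose
  n_major <- 2 * n - n_minor
  logp <- vapply(hets, function(h) {
    hom_min <- (n_minor - h) / 2
    hom_maj <- n - h - hom_min
    h * log(2) + lgamma(n + 1) -
      (lgamma(hom_min + 1) + lgamma(h + 1) + lgamma(hom_maj + 1))
  }, numeric(1))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  p_obs <- prob[match(het_obs, hets)]
  if (is.na(p_obs)) stop("heterozygote count inconsistent with allele counts")
  min(1, sum(prob[prob <= p_obs + 1e-12]))
}

#' Hardy-Weinberg tests for every SNP in a dataset
#'
#' @param dataset an encoded [cohort_dataset()].
#' @param controls_only evaluate on controls only (default `TRUE`, the usual
#'   case-control QC convention).
#' @param method passed to [hwe_test()].
#' @return data.frame (rsid, n0, n1, n2, p_value).
#' @export
hwe_test_dataset <- function(dataset, controls_only = TRUE,
                             method = "exact") {
  stopifnot(inherits(dataset, "cohort_dataset"), dataset$encoded)
  g <- dataset$genotypes
  if (controls_only) g <- g[dataset$phenotype$case_status == 0, , drop = FALSE]
  counts <- t(apply(g, 2L, function(col) {
    c(sum(col == 0, na.rm = TRUE), sum(col == 1, na.rm = TRUE),
      sum(col == 2, na.rm = TRUE))
  }))
  p <- apply(counts, 1L, function(cn) hwe_test(cn[1], cn[2], cn[3],
                                               method = method))
  data.frame(rsid = colnames(g), n0 = counts[, 1], n1 = counts[, 2],
             n2 = counts[, 3], p_value = p, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Greedy tag-SNP selection by r-squared binning
#'
#' Carlson-style binning: repeatedly take the unbinned SNP with the most
#' unbinned neighbors at r-squared >= `threshold` as the bin seed; the bin is
#' the seed plus those neighbors. The bin's tag is a priority SNP if one has
#' r-squared >= `threshold` with every other bin member, otherwise the member
#' maximizing its minimum r-squared to the rest of the bin. All ties are
#' broken by rsID order. `NA` r-squared entries are treated as below
#' threshold.
#'
#' @param ld an [pairwise_r2()] matrix (or any symmetric r-squared matrix
#'   with dimnames).
#' @param threshold binning threshold (default 0.8).
#' @param priority character vector of rsIDs preferred as tags (e.g. exonic
#'   or previously reported SNPs).
#' @return list of bins, each a list with `tag`, `members`, `seed`; the bins
#'   partition the SNP set.
#' @export
select_tags <- function(ld, threshold = 0.8, priority = character(0)) {
  snps <- colnames(ld)
  stopifnot(!is.null(snps))
  ld <- as.matrix(ld)
  ld[is.na(ld)] <- 0
  unbinned <- sort(snps)
  bins <- list()
  while (length(unbinned)) {
    neigh <- vapply(unbinned, function(s)
      sum(ld[s, setdiff(unbinned, s)] >= threshold), numeric(1))
    seed <- unbinned[which.max(neigh)]  # ties: first in rsID order
    members <- c(seed, setdiff(unbinned, seed)[
      ld[seed, setdiff(unbinned, seed)] >= threshold])
    members <- sort(members)
    tag <- choose_tag(ld, members, threshold, priority)
    bins[[length(bins) + 1L]] <- list(tag = tag, members = members,
                                      seed = seed)
    unbinned <- setdiff(unbinned, members)
  }
  bins
}

choose_tag <- function(ld, members, threshold, priority) {
  if (length(members) == 1L) return(members)
  covers_all <- function(s)
    all(ld[s, setdiff(members, s)] >= threshold)
  prio <- sort(intersect(members, priority))
  for (s in prio) if (covers_all(s)) return(s)
  min_r2 <- vapply(members, function(s)
    min(ld[s, setdiff(members, s)]), numeric(1))
  members[which.max(min_r2)]  # ties: first in rsID order
}

#' Write / read an LD matrix as long-format TSV (snp1, snp2, r2)
#'
#' The same dialect is accepted as the external r-squared source for prior
#' construction, so empirical LD can stand in for an external reference panel.
#'
#' @param ld matrix with dimnames (upper triangle is written).
#' @param path TSV file.
#' @return `write_ld_tsv`: the path, invisibly. `read_ld_tsv`: a data.frame
#'   (snp1, snp2, r2).
#' @export
write_ld_tsv <- function(ld, path) {
  idx <- which(upper.tri(ld), arr.ind = TRUE)
  long <- data.frame(snp1 = rownames(ld)[idx[, 1]],
                     snp2 = colnames(ld)[idx[, 2]],
                     r2 = ld[idx], stringsAsFactors = FALSE)
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_ld_tsv
#' @export
read_ld_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write tag bins as TSV (tag, member)
#' @param bins result of [select_tags()].
#' @param path TSV file.
#' @export
write_tag_bins <- function(bins, path) {
  long <- do.call(rbind, lapply(bins, function(b)
    data.frame(tag = b$tag, member = b$members, stringsAsFactors = FALSE)))
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
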