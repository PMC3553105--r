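#' Encode raw genotype calls additively
#'
#' Converts allele-pair calls to minor-allele counts (0/1/2), with the major
#' homozygote as the reference (0). The major allele is determined empirically
#' from allele frequencies over the whole dataset, before any stratification;
#' a 50/50 frequency tie is broken by lexicographic allele order (the smaller
#' allele is taken as the reference/major). Heterozygotes code 1 regardless of
#' within-call allele order.
#'
#' @param dataset a [cohort_dataset()] with raw calls, or a character matrix.
#' @return the dataset with a numeric 0/1/2 genotype matrix and an `encoding`
#'   table (rsid, major, minor); monomorphic SNPs encode all-0 with a warning
#'   (they fall to the MAF filter downstream).
#' @export
encode_additive <- function(dataset) {
  raw_matrix <- if (inherits(dataset, "cohort_dataset")) dataset$genotypes
                else dataset
  if (is.numeric(raw_matrix)) return(dataset)  # already encoded
  n_snp <- ncol(raw_matrix)
  enc <- matrix(NA_real_, nrow(raw_matrix), n_snp,
                dimnames = dimnames(raw_matrix))
  major <- minor <- character(n_snp)
  mono <- character(0)
  for (j in seq_len(n_snp)) {
    calls <- raw_matrix[, j]
    ok <- !is.na(calls)
    al <- unlist(strsplit(calls[ok], ""))
    alleles <- sort(unique(al))
    if (length(alleles) > 2L)
      stop("SNP ", colnames(raw_matrix)[j], " is not biallelic")
    if (length(alleles) <= 1L) {
      major[j] <- if (length(alleles)) alleles else NA_character_
      minor[j] <- NA_character_
      enc[ok, j] <- 0
      mono <- c(mono, colnames(raw_matrix)[j])
      next
    }
    freq1 <- mean(al == alleles[1L])
    # ties (freq exactly 0.5): lexicographically smaller allele is major
    major[j] <- if (freq1 >= 0.5) alleles[1L] else alleles[2L]
    minor[j] <- setdiff(alleles, major[j])
    cnt <- vapply(strsplit(calls[ok], ""), function(a) sum(a == minor[j]),
                  numeric(1))
    enc[ok, j] <- cnt
  }
  if (length(mono))
    warning("monomorphic SNP(s) encoded all-0: ",
            paste(utils::head(mono, 5L), collapse = ", "),
            if (length(mono) > 5L) ", ...")
  encoding <- data.frame(rsid = colnames(raw_matrix), major = major,
                         minor = minor, stringsAsFactors = FALSE)
  if (inherits(dataset, "cohort_dataset")) {
    dataset$genotypes <- enc
    dataset$encoded <- TRUE
    dataset$encoding <- encoding
    dataset
  } else structure(enc, encoding = encoding)
}

#' SNP quality-control filter
#'
#' Removes SNPs with genotype call rate below `call_rate_min`, minor allele
#' frequency below `maf_min`, or missing-call fraction above `missing_max`.
#' A SNP is removed iff it violates at least one rule; the report records all
#' violated rules per removed SNP.
#'
#' @param dataset a [cohort_dataset()] (encoded; raw calls are encoded first).
#' @param call_rate_min minimum per-SNP call rate (default 0.95).
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param missing_max maximum missing fraction (default 0.10).
#' @return list with the filtered `dataset` and a `report` data.frame of class
#'   `qc_report` (rsid, call_rate, maf, missing_frac, removed, reason).
#' @export
qc_filter_snps <- function(dataset, call_rate_min = 0.95, maf_min = 0.01,
                           missing_max = 0.10) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  dataset <- encode_additive(dataset)
  g <- dataset$genotypes
  missing_frac <- colMeans(is.na(g))
  call_rate <- 1 - missing_frac
  p <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  reasons <- mapply(function(cr, mf, mi) {
    r <- c(if (cr < call_rate_min) "call_rate",
           if (mf < maf_min) "maf",
           if (mi > missing_max) "missing_max")
    if (length(r)) paste(r, collapse = ",") else ""
  }, call_rate, maf, missing_frac)
  removed <- reasons != ""
  report <- data.frame(rsid = colnames(g), call_rate = call_rate,
                       maf = maf, missing_frac = missing_frac,
                       removed = removed, reason = reasons,
                       row.names = NULL, stringsAsFactors = FALSE)
  class(report) <- c("qc_report", "data.frame")
  attr(report, "n_removed") <- sum(removed)
  attr(report, "n_retained") <- sum(!removed)
  if (all(removed)) stop("all SNPs removed by QC filters")
  list(dataset = subset_cohort(dataset, snps = colnames(g)[!removed]),
       report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> ", attr(x, "n_retained"), " SNPs retained, ",
      attr(x, "n_removed"), " removed\n", sep = "")
  print.data.frame(utils::head(x[x$removed, ], 10L))
  invisible(x)
}

#' Write a QC report as TSV
#' @param report a `qc_report` from [qc_filter_snps()].
#' @param path output file.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Test independence of per-SNP missingness and case status
#'
#' For each SNP with at least one missing call, a Pearson chi-square test
#' (no continuity correction) of the 2x2 table missing-indicator x case
#' status. SNPs with no missing calls are reported as not applicable (`NA`).
#'
#' @param dataset an encoded [cohort_dataset()].
#' @return data.frame (rsid, n_missing, p_value).
#' @export
missingness_independence_test <- function(dataset) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  g <- dataset$genotypes
  status <- dataset$phenotype$case_status
  p <- apply(is.na(g), 2L, function(miss) {
    if (!any(miss)) return(NA_real_)
    tab <- table(factor(miss, c(FALSE, TRUE)), factor(status, c(0, 1)))
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  })
  data.frame(rsid = colnames(g), n_missing = colSums(is.na(g)),
             p_value = as.numeric(p), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Drop subjects with any missing call among a set of SNPs
#'
#' @param dataset a [cohort_dataset()].
#' @param snp_subset rsIDs over which complete genotypes are required
#'   (default: all SNPs in the dataset).
#' @return the complete-case `cohort_dataset`; retained/removed counts by case
#'   status are attached as attribute `"complete_case_counts"` and logged.
#' @export
complete_case_filter <- function(dataset, snp_subset = NULL) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  if (is.null(snp_subset)) snp_subset <- colnames(dataset$genotypes)
  if (!length(snp_subset)) stop("snp_subset must be nonempty")
  g <- dataset$genotypes[, snp_subset, drop = FALSE]
  keep <- !apply(is.na(g), 1L, any)
  if (!any(keep)) stop("no subjects remain after complete-case filtering")
  status <- dataset$phenotype$case_status
  counts <- c(cases_kept = sum(keep & status == 1),
              controls_kept = sum(keep & status == 0),
              cases_dropped = sum(!keep & status == 1),
              controls_dropped = sum(!keep & status == 0))
  message("complete-case filter: kept ", counts["cases_kept"], " cases / ",
          counts["controls_kept"], " controls (dropped ",
          sum(counts[3:4]), ")")
  out <- subset_cohort(dataset, subjects = subject_ids(dataset)[keep])
  attr(out, "complete_case_counts") <- counts
  out
}
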