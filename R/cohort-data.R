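#' Cohort dataset container
#'
#' Bundles the four aligned components of a case-control cohort: a genotype
#' matrix (raw allele-pair calls or additively encoded 0/1/2 counts), a SNP
#' annotation table, a phenotype/covariate table, and a nutrient intake table.
#' All components are keyed by subject id and kept in the same subject order.
#'
#' @param genotypes matrix (subjects x SNPs). Either character allele pairs
#'   (e.g. `"AG"`, `NA` for no-calls) or numeric minor-allele counts 0/1/2.
#'   Row names are subject ids, column names rsIDs.
#' @param annotation data.frame with columns `rsid`, `chrom`, `pos` (1-based),
#'   `gene`, and logical `priority`; one row per genotyped SNP.
#' @param phenotype data.frame with columns `subject_id`, `case_status`
#'   (1 = case), `sex` (`"male"`/`"female"`), `age`, `family_history` (1 = at
#'   least one affected first-degree relative), `smoking_status`
#'   (`"never"`/`"former"`/`"current"`), `pack_years`, `cessation_age`,
#'   `ets_exposed`. Smoking-dependent fields may be `NA` where not applicable.
#' @param nutrients data.frame of daily intakes, row names subject ids; must
#'   contain an `energy` column (kcal) before adjustment; `alcohol` in g/day.
#'
#' @return An object of class `cohort_dataset`.
#' @export
cohort_dataset <- function(genotypes, annotation, phenotype, nutrients) {
  stopifnot(is.matrix(genotypes), is.data.frame(annotation),
            is.data.frame(phenotype))
  ids <- phenotype$subject_id
  if (anyDuplicated(ids))
    stop("duplicate subject id: ", ids[duplicated(ids)][1L])
  if (!identical(rownames(genotypes), as.character(ids)))
    stop("genotype rows and phenotype subjects are not aligned")
  if (!is.null(nutrients) &&
      !identical(rownames(nutrients), as.character(ids)))
    stop("nutrient rows and phenotype subjects are not aligned")
  missing_ann <- setdiff(colnames(genotypes), annotation$rsid)
  if (length(missing_ann))
    stop("SNPs without annotation: ", paste(missing_ann, collapse = ", "))
  annotation <- annotation[match(colnames(genotypes), annotation$rsid), ,
                           drop = FALSE]
  rownames(annotation) <- NULL
  structure(
    list(genotypes = genotypes, annotation = annotation,
         phenotype = phenotype, nutrients = nutrients,
         encoded = is.numeric(genotypes), encoding = NULL),
    class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("<cohort_dataset> ", nrow(x$phenotype), " subjects (",
      sum(x$phenotype$case_status == 1), " cases), ",
      ncol(x$genotypes), " SNPs, ",
      if (is.null(x$nutrients)) 0L else ncol(x$nutrients), " nutrients; ",
      if (x$encoded) "encoded 0/1/2" else "raw calls", "\n", sep = "")
  invisible(x)
}

#' @export
dim.cohort_dataset <- function(x) dim(x$genotypes)

subject_ids <- function(dataset) as.character(dataset$phenotype$subject_id)

#' Subset a cohort dataset by subjects and/or SNPs
#'
#' @param dataset a [cohort_dataset()].
#' @param subjects character vector of subject ids to keep (default all).
#' @param snps character vector of rsIDs to keep (default all).
#' @return the filtered `cohort_dataset`.
#' @export
subset_cohort <- function(dataset, subjects = NULL, snps = NULL) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  if (is.null(subjects)) subjects <- subject_ids(dataset)
  if (is.null(snps)) snps <- colnames(dataset$genotypes)
  keep_s <- subject_ids(dataset) %in% subjects
  keep_g <- colnames(dataset$genotypes) %in% snps
  out <- dataset
  out$genotypes <- dataset$genotypes[keep_s, keep_g, drop = FALSE]
  out$annotation <- dataset$annotation[keep_g, , drop = FALSE]
  out$phenotype <- dataset$phenotype[keep_s, , drop = FALSE]
  rownames(out$phenotype) <- NULL
  if (!is.null(dataset$nutrients))
    out$nutrients <- dataset$nutrients[keep_s, , drop = FALSE]
  if (!is.null(dataset$encoding))
    out$encoding <- dataset$encoding[keep_g, , drop = FALSE]
  out
}
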