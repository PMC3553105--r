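#' Read and align the four cohort input files
#'
#' Reads a genotype table, a SNP annotation table, a phenotype/covariate table
#' and a nutrient table, aligns them on subject id, and returns a
#' [cohort_dataset()]. Subjects present in some files but not all are reported
#' and dropped (the intersection is kept). Genotype calls are validated
#' against the observed (or annotated) alleles per SNP.
#'
#' Two genotype dialects are supported:
#' \describe{
#'   \item{`"delimited"`}{tab-delimited, header row `subject_id` + one column
#'     per rsID, entries allele pairs such as `AG`; missing as `NA`, `--` or
#'     `00`.}
#'   \item{`"ped"`}{PLINK-style whitespace-delimited `.ped` (FID IID PAT MAT
#'     SEX PHENO then two allele columns per SNP, `0` = missing) with the SNP
#'     order taken from the companion `.map` file (chrom, rsid, cM, pos); pass
#'     the `.ped` path, the `.map` is found by extension swap.}
#' }
#'
#' @param genotype_path path to the genotype file.
#' @param annotation_path TSV with columns rsid, chrom, pos, gene, priority.
#' @param phenotype_path CSV with a header (see [cohort_dataset()] fields).
#' @param nutrient_path CSV with a header: subject_id then one numeric column
#'   per nutrient (must include `energy`); `NULL` for a genotype-only study.
#' @param format_dialect `"delimited"` or `"ped"`.
#' @param col_map optional named character vector mapping canonical phenotype
#'   column names to the names used in the file (e.g.
#'   `c(case_status = "status")`), as from a YAML config.
#' @return a [cohort_dataset()] with raw (unencoded) genotype calls.
#' @export
read_cohort <- function(genotype_path, annotation_path, phenotype_path,
                        nutrient_path = NULL,
                        format_dialect = c("delimited", "ped"),
                        col_map = NULL) {
  format_dialect <- match.arg(format_dialect)
  for (f in c(genotype_path, annotation_path, phenotype_path, nutrient_path))
    if (!file.exists(f)) stop("file not found: ", f)

  geno <- switch(format_dialect,
                 delimited = read_genotypes_delim(genotype_path),
                 ped = read_genotypes_ped(genotype_path))
  annotation <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  need <- c("rsid", "chrom", "pos", "gene")
  if (!all(need %in% names(annotation)))
    stop("annotation file ", annotation_path, " lacks columns: ",
         paste(setdiff(need, names(annotation)), collapse = ", "))
  if (is.null(annotation$priority)) annotation$priority <- FALSE
  annotation$priority <- as.logical(annotation$priority)
  annotation$chrom <- as.character(annotation$chrom)
  if (any(annotation$pos < 0) || any(annotation$pos != round(annotation$pos)))
    stop("annotation positions must be nonnegative integers")

  phenotype <- utils::read.csv(phenotype_path, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      j <- match(col_map[[canon]], names(phenotype))
      if (!is.na(j)) names(phenotype)[j] <- canon
    }
  }
  if (!"subject_id" %in% names(phenotype))
    stop("phenotype file lacks a subject_id column")
  phenotype$subject_id <- as.character(phenotype$subject_id)
  if (anyDuplicated(phenotype$subject_id))
    stop("duplicate subject id in ", phenotype_path, ": ",
         phenotype$subject_id[duplicated(phenotype$subject_id)][1L])
  for (f in c("pack_years", "cessation_age", "ets_exposed"))
    if (is.null(phenotype[[f]])) phenotype[[f]] <- NA_real_

  nutrients <- NULL
  if (!is.null(nutrient_path)) {
    nutrients <- utils::read.csv(nutrient_path, stringsAsFactors = FALSE)
    if (!"subject_id" %in% names(nutrients))
      stop("nutrient file lacks a subject_id column")
    if (anyDuplicated(nutrients$subject_id))
      stop("duplicate subject id in ", nutrient_path)
    rownames(nutrients) <- as.character(nutrients$subject_id)
    nutrients$subject_id <- NULL
  }

  ids <- Reduce(intersect, Filter(Negate(is.null), list(
    rownames(geno), phenotype$subject_id,
    if (!is.null(nutrients)) rownames(nutrients))))
  all_ids <- unique(c(rownames(geno), phenotype$subject_id,
                      if (!is.null(nutrients)) rownames(nutrients)))
  dropped <- setdiff(all_ids, ids)
  if (length(dropped))
    warning("dropping ", length(dropped),
            " subject(s) not present in every input file: ",
            paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ...")
  if (!length(ids)) stop("no subjects shared across the input files")

  geno <- geno[ids, , drop = FALSE]
  phenotype <- phenotype[match(ids, phenotype$subject_id), , drop = FALSE]
  rownames(phenotype) <- NULL
  if (!is.null(nutrients)) nutrients <- nutrients[ids, , drop = FALSE]

  validate_biallelic(geno, annotation)
  cohort_dataset(geno, annotation, phenotype, nutrients)
}

read_genotypes_delim <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", "--", "00", ""))
  if (!"subject_id" %in% names(tab))
    stop("genotype file ", path, " lacks a subject_id column")
  if (anyDuplicated(tab$subject_id))
    stop("duplicate subject id in ", path)
  ids <- as.character(tab$subject_id)
  tab$subject_id <- NULL
  geno <- as.matrix(tab)
  rownames(geno) <- ids
  bad <- which(!is.na(geno) & nchar(geno) != 2L, arr.ind = TRUE)
  if (nrow(bad))
    stop("malformed genotype call in ", path, " row ", bad[1L, 1L] + 1L,
         " (subject ", ids[bad[1L, 1L]], ", SNP ",
         colnames(geno)[bad[1L, 2L]], "): '", geno[bad[1L, , drop = FALSE]],
         "'")
  geno
}

read_genotypes_ped <- function(ped_path) {
  map_path <- sub("\\.ped$", ".map", ped_path)
  if (identical(map_path, ped_path) || !file.exists(map_path))
    stop("companion .map file not found for ", ped_path)
  map <- utils::read.table(map_path, stringsAsFactors = FALSE)
  rsids <- map[[2L]]
  rows <- strsplit(trimws(readLines(ped_path)), "[ \t]+")
  nfield <- 6L + 2L * length(rsids)
  geno <- matrix(NA_character_, length(rows), length(rsids))
  ids <- character(length(rows))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) != nfield)
      stop("malformed row in ", ped_path, " line ", i, ": expected ",
           nfield, " fields, got ", length(r))
    ids[i] <- r[2L]
    a1 <- r[seq(7L, nfield, by = 2L)]
    a2 <- r[seq(8L, nfield, by = 2L)]
    call <- paste0(a1, a2)
    call[a1 == "0" | a2 == "0"] <- NA_character_
    geno[i, ] <- call
  }
  if (anyDuplicated(ids)) stop("duplicate subject id in ", ped_path)
  dimnames(geno) <- list(ids, rsids)
  geno
}

# Each SNP must carry at most two distinct alleles; if the annotation has an
# `alleles` column ("A/G"), observed calls must come from that pair.
validate_biallelic <- function(geno, annotation) {
  for (j in seq_len(ncol(geno))) {
    calls <- geno[, j]
    alleles <- unique(unlist(strsplit(calls[!is.na(calls)], "")))
    rsid <- colnames(geno)[j]
    if (!is.null(annotation$alleles)) {
      ann <- annotation$alleles[match(rsid, annotation$rsid)]
      if (!is.na(ann)) {
        allowed <- strsplit(ann, "/")[[1L]]
        extra <- setdiff(alleles, allowed)
        if (length(extra))
          stop("SNP ", rsid, ": allele(s) ", paste(extra, collapse = ","),
               " outside annotated ", ann)
      }
    }
    if (length(alleles) > 2L)
      stop("SNP ", rsid, " is not biallelic: observed alleles ",
           paste(sort(alleles), collapse = ","))
  }
  invisible(TRUE)
}

#' Write a cohort dataset as the four input files
#'
#' Inverse of [read_cohort()] for the `"delimited"` dialect; used by the
#' synthetic generator so simulated studies round-trip through ingestion.
#'
#' @param dataset a [cohort_dataset()] with raw (character) genotype calls.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of the four file paths.
#' @export
write_cohort_files <- function(dataset, dir) {
  stopifnot(inherits(dataset, "cohort_dataset"), !dataset$encoded)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genotypes = file.path(dir, "genotypes.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             phenotype = file.path(dir, "phenotype.csv"),
             nutrients = file.path(dir, "nutrients.csv"))
  gt <- data.frame(subject_id = rownames(dataset$genotypes),
                   dataset$genotypes, check.names = FALSE)
  utils::write.table(gt, paths["genotypes"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(dataset$annotation, paths["annotation"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(dataset$phenotype, paths["phenotype"], row.names = FALSE)
  if (!is.null(dataset$nutrients)) {
    nt <- data.frame(subject_id = rownames(dataset$nutrients),
                     dataset$nutrients, check.names = FALSE)
    utils::write.csv(nt, paths["nutrients"], row.names = FALSE)
  } else paths <- paths[1:3]
  invisible(paths)
}
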