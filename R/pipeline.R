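#' Stage-2 screen: stochastic search over one candidate block
#'
#' Runs SSVS over a single block of candidates (the SNPs, or the nutrients)
#' plus the stratum's forced-in covariates, and advances every variable with
#' posterior inclusion probability above `threshold`.
#'
#' @param design a [stratum_design()] whose selectable columns are the
#'   candidate block.
#' @param prior a [assemble_prior()] spec for the block (LD-informed R for
#'   the SNP screen, identity for the nutrient screen).
#' @param config a [sampler_config()].
#' @param threshold PPI screening threshold, strict (default 0.35).
#' @param stage label recorded on the result.
#' @return object of class `stage_result`: list with `stage`, `candidates`,
#'   `summary` (a [posterior_summary()]), `advanced`.
#' @export
stage2_screen <- function(design, prior, config, threshold = 0.35,
                          stage = "screen") {
  chains <- run_ssvs(design, prior, config)
  summ <- posterior_summary(chains, ppi_threshold = threshold,
                            bf_threshold = NULL)
  advanced <- select_variables(summ, ppi_threshold = threshold)
  structure(list(stage = stage, candidates = design$ids, summary = summ,
                 advanced = as.character(advanced), chains = chains),
            class = "stage_result")
}

#' @export
print.stage_result <- function(x, ...) {
  cat("<stage_result:", x$stage, "> ", length(x$candidates),
      " candidates -> ", length(x$advanced), " advanced\n", sep = "")
  invisible(x)
}

#' Pairwise SNP-by-nutrient interaction block with collinearity pruning
#'
#' Builds the interaction columns as (standardized nutrient) x (raw additive
#' SNP code), each then standardized. A product is dropped when its squared
#' correlation with any main-effect column or any earlier-kept interaction
#' exceeds `collinearity_r2`; candidates are visited in lexicographic
#' (snp, nutrient) order so pruning is deterministic. Products involving a
#' constant column are dropped with a reason.
#'
#' @param snp_matrix subjects x SNPs additive codes (advanced SNPs).
#' @param nutrient_matrix subjects x nutrients (advanced nutrients,
#'   energy-adjusted).
#' @param collinearity_r2 squared-correlation pruning cutoff (default 0.8).
#' @return list with `X_int` (kept interaction columns, named
#'   `"<nutrient>*<snp>"`), and `pruned` data.frame (id, reason).
#' @export
build_interactions <- function(snp_matrix, nutrient_matrix,
                               collinearity_r2 = 0.8) {
  if (!NCOL(snp_matrix) || !NCOL(nutrient_matrix))
    return(list(X_int = matrix(numeric(0), NROW(snp_matrix), 0),
                pruned = data.frame(id = character(0),
                                    reason = character(0))))
  snp_matrix <- as.matrix(snp_matrix)
  nutrient_matrix <- as.matrix(nutrient_matrix)
  snps <- sort(colnames(snp_matrix))
  nuts <- colnames(nutrient_matrix)
  zn <- scale(nutrient_matrix)
  mains <- cbind(snp_matrix, nutrient_matrix)
  kept <- list(); pruned <- list()
  for (s in snps) for (nu in sort(nuts)) {
    id <- paste0(nu, "*", s)
    col <- zn[, nu] * snp_matrix[, s]
    if (stats::sd(col) == 0 || stats::sd(snp_matrix[, s]) == 0) {
      pruned[[id]] <- "constant"
      next
    }
    col <- drop(scale(col))
    ref <- cbind(mains, do.call(cbind, kept))
    r2 <- suppressWarnings(stats::cor(col, ref))^2
    r2[is.na(r2)] <- 0
    if (any(r2 > collinearity_r2)) {
      pruned[[id]] <- paste0("collinear_with:",
                             colnames(ref)[which.max(r2)])
      next
    }
    kept[[id]] <- col
  }
  X_int <- if (length(kept)) do.call(cbind, kept)
           else matrix(numeric(0), nrow(snp_matrix), 0)
  if (length(kept)) colnames(X_int) <- names(kept)
  list(X_int = X_int,
       pruned = data.frame(id = names(pruned),
                           reason = unlist(pruned, use.names = FALSE),
                           stringsAsFactors = FALSE))
}

#' Stage-3 joint model: mains, interactions, and the final selection
#'
#' Runs SSVS jointly over the advanced SNPs, advanced nutrients and their
#' unpruned pairwise interactions (plus forced covariates), and selects the
#' final model by marginal Bayes factor > `bf_threshold`. If the chains do
#' not agree (see [convergence_check()]) the run continues with a warning
#' and per-chain summaries attached.
#'
#' @param response binary case status for the stratum.
#' @param X_forced forced covariate matrix (no intercept).
#' @param snp_matrix,nutrient_matrix advanced main-effect columns.
#' @param snp_R prior correlation among the advanced SNPs (identity used for
#'   nutrients and interactions).
#' @param config a [sampler_config()].
#' @param bf_threshold final-model Bayes-factor rule, strict (default 3).
#' @param collinearity_r2 passed to [build_interactions()].
#' @param prior_args named list overriding [assemble_prior()] defaults.
#' @return a `stage_result` with `summary`, final `advanced` set, `pruned`
#'   interactions and the expected FDR of the final set.
#' @export
stage3_joint <- function(response, X_forced, snp_matrix, nutrient_matrix,
                         snp_R = NULL, config = sampler_config(),
                         bf_threshold = 3, collinearity_r2 = 0.8,
                         prior_args = list()) {
  inter <- build_interactions(snp_matrix, nutrient_matrix, collinearity_r2)
  X_sel <- cbind(as.matrix(snp_matrix), as.matrix(nutrient_matrix),
                 inter$X_int)
  if (!ncol(X_sel)) stop("stage 3 has no candidate variables")
  ids <- colnames(X_sel)
  m <- length(ids)
  R <- diag(m)
  dimnames(R) <- list(ids, ids)
  if (!is.null(snp_R)) {
    sn <- intersect(colnames(as.matrix(snp_matrix)), rownames(snp_R))
    R[sn, sn] <- snp_R[sn, sn]
    R <- repair_correlation(R)
  }
  design <- stratum_design(response, X_forced, X_sel,
                           snp_cols = colnames(as.matrix(snp_matrix)))
  prior <- do.call(assemble_prior,
                   c(list(selectable_ids = ids,
                          forced_ids = colnames(design$X_forced),
                          R = R), prior_args))
  chains <- run_ssvs(design, prior, config)
  summ <- posterior_summary(chains, bf_threshold = bf_threshold)
  conv <- attr(summ, "convergence")
  if (length(chains$chains) >= 2L && !isTRUE(conv$pooled))
    warning("chains disagree (min PPI correlation ",
            signif(conv$correlation, 3),
            "); pooled summary reported, inspect per-chain PPIs")
  final <- select_variables(summ, bf_threshold = bf_threshold)
  structure(list(stage = "joint", candidates = ids, summary = summ,
                 advanced = as.character(final), pruned = inter$pruned,
                 efdr = attr(summ, "efdr"), convergence = conv,
                 chains = chains),
            class = "stage_result")
}

#' Run the full three-stage pipeline on a cohort
#'
#' Orchestrates the analysis per smoking stratum: additive encoding, SNP QC,
#' missingness-independence check, complete-case filtering, tag-SNP
#' selection, Hardy-Weinberg screening, energy adjustment, stratification,
#' then per stratum a stage-2 SNP screen (LD-informed prior correlation), a
#' stage-2 nutrient screen (identity prior), and the stage-3 joint model
#' with SNP-by-nutrient interactions. Deterministic given `seed`.
#'
#' @param dataset a [cohort_dataset()] (raw or encoded), e.g. from
#'   [read_cohort()] or [generate_study()].
#' @param config a [sampler_config()]; its seed governs the whole run.
#' @param screen_threshold stage-2 PPI rule (default 0.35, strict).
#' @param bf_threshold stage-3 Bayes-factor rule (default 3, strict).
#' @param tag_r2 tag-SNP binning threshold (default 0.8).
#' @param hwe_alpha Hardy-Weinberg exclusion level in controls (default
#'   0.001).
#' @param collinearity_r2 interaction pruning cutoff (default 0.8).
#' @param external_r2 optional external r-squared table for the prior
#'   (long-format data.frame); defaults to the empirical LD of the data.
#' @param nutrient_cols nutrient columns eligible for selection (default:
#'   all energy-adjusted columns plus the alcohol drinker indicator).
#' @param prior_args named list overriding [assemble_prior()] defaults.
#' @return object of class `pipeline_result`: per-stratum list of stage
#'   results plus QC/tagging bookkeeping and the run metadata.
#' @export
run_full_pipeline <- function(dataset, config = sampler_config(),
                              screen_threshold = 0.35, bf_threshold = 3,
                              tag_r2 = 0.8, hwe_alpha = 0.001,
                              collinearity_r2 = 0.8, external_r2 = NULL,
                              nutrient_cols = NULL, prior_args = list()) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  dataset <- encode_additive(dataset)
  qc <- qc_filter_snps(dataset)
  miss <- missingness_independence_test(qc$dataset)
  cc <- complete_case_filter(qc$dataset)
  ld <- pairwise_r2(cc)
  priority <- cc$annotation$rsid[cc$annotation$priority]
  bins <- select_tags(ld, threshold = tag_r2, priority = priority)
  tags <- vapply(bins, `[[`, character(1), "tag")
  hwe <- hwe_test_dataset(subset_cohort(cc, snps = tags))
  tags <- setdiff(tags, hwe$rsid[hwe$p_value < hwe_alpha])
  ds <- subset_cohort(cc, snps = tags)
  has_nutrients <- !is.null(ds$nutrients)
  if (has_nutrients) {
    ds <- energy_adjust(ds)
    if (is.null(nutrient_cols)) {
      nutrient_cols <- c("alcohol",
                         attr(ds$nutrients, "energy_adjusted"))
      nutrient_cols <- intersect(nutrient_cols, names(ds$nutrients))
    }
  }
  r2_source <- if (is.null(external_r2)) ld[tags, tags] else external_r2
  strata <- stratify_smoking(ds)
  results <- list()
  for (nm in names(strata)) {
    sds <- strata[[nm]]
    results[[nm]] <- run_stratum(sds, nm, nutrient_cols, r2_source, config,
                                 screen_threshold, bf_threshold,
                                 collinearity_r2, prior_args)
  }
  structure(list(strata = results, qc_report = qc$report,
                 missingness = miss, tag_bins = bins, tags = tags,
                 hwe = hwe,
                 meta = list(seed = config$seed, n_iter = config$n_iter,
                             n_chains = config$n_chains,
                             algorithm = config$algorithm,
                             screen_threshold = screen_threshold,
                             bf_threshold = bf_threshold, tag_r2 = tag_r2,
                             hwe_alpha = hwe_alpha,
                             collinearity_r2 = collinearity_r2,
                             package_version =
                               as.character(utils::packageVersion("folatessvs")))),
            class = "pipeline_result")
}

run_stratum <- function(sds, stratum, nutrient_cols, r2_source, config,
                        screen_threshold, bf_threshold, collinearity_r2,
                        prior_args) {
  forced <- attr(sds, "forced")
  y <- sds$phenotype$case_status
  geno <- sds$genotypes
  # drop columns made constant by stratification
  geno <- geno[, apply(geno, 2L, stats::sd) > 0, drop = FALSE]
  out <- list(stratum = stratum,
              n_cases = sum(y == 1), n_controls = sum(y == 0))

  snp_ids <- colnames(geno)
  R_snp <- build_prior_correlation(snp_ids, sds$annotation, r2_source)
  snp_design <- stratum_design(y, forced, geno, snp_cols = snp_ids)
  snp_prior <- do.call(assemble_prior,
                       c(list(selectable_ids = snp_ids,
                              forced_ids = colnames(snp_design$X_forced),
                              R = R_snp), prior_args))
  out$snp_screen <- stage2_screen(snp_design, snp_prior, config,
                                  screen_threshold, stage = "screen_snps")

  adv_nut <- character(0)
  nut_mat <- NULL
  if (!is.null(sds$nutrients) && length(nutrient_cols)) {
    nut_mat <- build_nutrient_matrix(sds, nutrient_cols)
    keep <- !apply(is.na(nut_mat), 1L, any)
    if (sum(keep) >= 10L) {
      nut_design <- stratum_design(y[keep],
                                   forced[keep, , drop = FALSE],
                                   nut_mat[keep, , drop = FALSE])
      nut_prior <- do.call(assemble_prior,
                           c(list(selectable_ids = colnames(nut_mat),
                                  forced_ids = colnames(nut_design$X_forced),
                                  R = NULL), prior_args))
      out$nutrient_screen <- stage2_screen(nut_design, nut_prior, config,
                                           screen_threshold,
                                           stage = "screen_nutrients")
      adv_nut <- out$nutrient_screen$advanced
    }
  }

  adv_snp <- out$snp_screen$advanced
  if (!length(adv_snp) && !length(adv_nut)) {
    out$joint <- NULL
    message("stratum ", stratum, ": no variables advanced to stage 3")
    return(out)
  }
  if (!is.null(nut_mat) && length(adv_nut)) {
    keep <- !apply(is.na(nut_mat[, adv_nut, drop = FALSE]), 1L, any)
  } else keep <- rep(TRUE, length(y))
  out$joint <- stage3_joint(
    y[keep], forced[keep, , drop = FALSE],
    geno[keep, adv_snp, drop = FALSE],
    if (length(adv_nut)) nut_mat[keep, adv_nut, drop = FALSE]
    else matrix(numeric(0), sum(keep), 0),
    snp_R = if (length(adv_snp) >= 2L)
      build_prior_correlation(adv_snp, sds$annotation, r2_source),
    config = config, bf_threshold = bf_threshold,
    collinearity_r2 = collinearity_r2, prior_args = prior_args)
  out
}

build_nutrient_matrix <- function(sds, nutrient_cols) {
  nut <- sds$nutrients
  m <- as.matrix(nut[, setdiff(nutrient_cols, "alcohol"), drop = FALSE])
  if ("alcohol" %in% nutrient_cols && "alcohol" %in% names(nut)) {
    drinker <- as.numeric(categorize_alcohol(nut$alcohol)$binary ==
                            "drinker")
    m <- cbind(m, alcohol = drinker)
  }
  rownames(m) <- rownames(nut)
  m
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> seed ", x$meta$seed, ", ", length(x$tags),
      " tag SNPs\n", sep = "")
  for (nm in names(x$strata)) {
    s <- x$strata[[nm]]
    cat("  ", nm, ": ", s$n_cases, " cases/", s$n_controls, " controls; ",
        "stage2 SNPs ", length(s$snp_screen$advanced),
        if (!is.null(s$nutrient_screen))
          paste0(", nutrients ", length(s$nutrient_screen$advanced)),
        "; final ",
        if (is.null(s$joint)) "(empty)"
        else paste(length(s$joint$advanced), "variable(s)"), "\n", sep = "")
  }
  invisible(x)
}

#' Write a pipeline results bundle to a directory
#'
#' TSV reports per stratum and stage, the QC report, tag bins, and a JSON
#' metadata file recording seeds, thresholds and versions.
#'
#' @param result a [run_full_pipeline()] result.
#' @param dir output directory (created).
#' @return invisibly, the directory.
#' @export
write_results_bundle <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_qc_report(result$qc_report, file.path(dir, "qc_report.tsv"))
  write_tag_bins(result$tag_bins, file.path(dir, "tag_bins.tsv"))
  utils::write.table(result$hwe, file.path(dir, "hwe.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (nm in names(result$strata)) {
    s <- result$strata[[nm]]
    for (st in c("snp_screen", "nutrient_screen", "joint"))
      if (!is.null(s[[st]]))
        write_posterior_summary(s[[st]]$summary,
                                file.path(dir, paste0(nm, "_", st, ".tsv")))
  }
  jsonlite::write_json(result$meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
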