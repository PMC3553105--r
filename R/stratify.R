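#' Stratify a cohort by smoking status
#'
#' Splits the dataset into never, former and current smoker strata and
#' attaches each stratum's forced-in covariate design:
#' \itemize{
#'   \item never: sex, age, family history, environmental tobacco smoke;
#'   \item former: sex, age, family history, age-at-cessation factor
#'     (stopped before age 40 / between 40 and 53 / at 54 or later);
#'   \item current: sex, age, family history, pack-year factor
#'     (<27 / 27-53 / 54-82 / >=83).
#' }
#' Factors are dummy-coded against their first level. Former smokers with a
#' missing cessation age (and current smokers with missing pack years) are
#' dropped with a warning.
#'
#' @param dataset a [cohort_dataset()].
#' @return named list of three `cohort_dataset`s (`never`, `former`,
#'   `current`), each with a numeric forced-covariate matrix in attribute
#'   `"forced"` (intercept excluded).
#' @export
stratify_smoking <- function(dataset) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  ph <- dataset$phenotype
  if (!all(ph$smoking_status %in% c("never", "former", "current")))
    stop("smoking_status must be never/former/current")
  out <- list()
  for (stratum in c("never", "former", "current")) {
    in_str <- ph$smoking_status == stratum
    sub <- ph[in_str, , drop = FALSE]
    drop <- rep(FALSE, nrow(sub))
    if (stratum == "former") drop <- is.na(sub$cessation_age)
    if (stratum == "current") drop <- is.na(sub$pack_years)
    if (stratum == "never") drop <- is.na(sub$ets_exposed)
    if (any(drop))
      warning(sum(drop), " ", stratum,
              "-smoker subject(s) dropped for missing stratum covariate")
    sub <- sub[!drop, , drop = FALSE]
    ds <- subset_cohort(dataset, subjects = as.character(sub$subject_id))
    attr(ds, "forced") <- forced_covariates(sub, stratum)
    attr(ds, "stratum") <- stratum
    out[[stratum]] <- ds
  }
  out
}

#' Forced-in covariate matrix for one smoking stratum
#'
#' @param pheno phenotype data.frame restricted to one stratum.
#' @param stratum one of `"never"`, `"former"`, `"current"`.
#' @return numeric matrix (no intercept column), factors dummy-coded against
#'   the first level.
#' @export
forced_covariates <- function(pheno, stratum) {
  base <- data.frame(
    sex = as.integer(pheno$sex == "male"),
    age = as.numeric(pheno$age),
    family_history = as.integer(pheno$family_history))
  extra <- switch(stratum,
    never = data.frame(ets = as.integer(pheno$ets_exposed)),
    former = {
      f <- cessation_age_category(pheno$cessation_age)
      as.data.frame(stats::model.matrix(~f)[, -1L, drop = FALSE])
    },
    current = {
      f <- pack_year_category(pheno$pack_years)
      as.data.frame(stats::model.matrix(~f)[, -1L, drop = FALSE])
    })
  names(extra) <- sub("^f", "", names(extra))
  m <- as.matrix(cbind(base, extra))
  rownames(m) <- as.character(pheno$subject_id)
  m
}

#' Age-at-smoking-cessation category (former smokers)
#' @param cessation_age numeric, age when the subject quit smoking.
#' @return factor with levels `"<40"`, `"40-53"`, `">=54"`.
#' @export
cessation_age_category <- function(cessation_age) {
  cut(cessation_age, breaks = c(-Inf, 40, 54, Inf), right = FALSE,
      labels = c("<40", "40-53", ">=54"))
}

#' Pack-year category (current smokers)
#' @param pack_years numeric pack years smoked.
#' @return factor with levels `"<27"`, `"27-53"`, `"54-82"`, `">=83"`.
#' @export
pack_year_category <- function(pack_years) {
  cut(pack_years, breaks = c(-Inf, 27, 54, 83, Inf), right = FALSE,
      labels = c("<27", "27-53", "54-82", ">=83"))
}
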