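#' Case/control descriptive summary table
#'
#' Builds the standard first-table comparison of cases and controls:
#' categorical variables as n (%) per level with a chi-square p-value (Yates
#' continuity correction for 2x2 tables, plain Pearson for larger ones),
#' continuous demographic variables as mean (SD) with a two-sample t-test,
#' and nutrient intakes as medians with a Wilcoxon rank-sum test (exact when
#' both arms have fewer than 25 subjects, normal approximation with tie
#' correction otherwise). Subjects missing a variable are dropped from that
#' variable's comparison only.
#'
#' @param dataset a [cohort_dataset()], or `NULL` when `variables` supplies
#'   data directly.
#' @param variables named list describing what to summarize. Each element is
#'   a list with `kind` (`"categorical"`, `"continuous"`, `"nutrient"`) and
#'   `values` (vector aligned with subjects) — or, when `dataset` is given,
#'   `source` (`"phenotype"` or `"nutrients"`) and `column`. Defaults to all
#'   phenotype demographics plus all nutrient columns.
#' @return data.frame of class `descriptive_summary` with columns variable,
#'   level, cases, controls, p_value.
#' @export
descriptive_summary <- function(dataset, variables = NULL) {
  status <- dataset$phenotype$case_status
  if (length(unique(status)) < 2L || min(table(status)) < 2L)
    stop("need at least 2 subjects per arm")
  if (is.null(variables)) variables <- default_summary_variables(dataset)
  rows <- list()
  for (nm in names(variables)) {
    v <- variables[[nm]]
    vals <- if (!is.null(v$values)) v$values
            else if (v$source == "phenotype") dataset$phenotype[[v$column]]
            else dataset$nutrients[[v$column]]
    ok <- !is.na(vals)
    x <- vals[ok]; st <- status[ok]
    if (v$kind == "categorical") {
      tab <- table(factor(x), factor(st, c(1, 0)))
      p <- chisq_p(tab)
      pct <- prop.table(tab, margin = 2L) * 100
      for (lev in rownames(tab))
        rows[[length(rows) + 1L]] <- data.frame(
          variable = nm, level = lev,
          cases = sprintf("%d (%.1f)", tab[lev, 1L], pct[lev, 1L]),
          controls = sprintf("%d (%.1f)", tab[lev, 2L], pct[lev, 2L]),
          p_value = p, stringsAsFactors = FALSE)
    } else if (v$kind == "continuous") {
      p <- stats::t.test(x[st == 1], x[st == 0])$p.value
      rows[[length(rows) + 1L]] <- data.frame(
        variable = nm, level = "mean (SD)",
        cases = sprintf("%.1f (%.1f)", mean(x[st == 1]), stats::sd(x[st == 1])),
        controls = sprintf("%.1f (%.1f)", mean(x[st == 0]), stats::sd(x[st == 0])),
        p_value = p, stringsAsFactors = FALSE)
    } else {  # nutrient: median + rank-sum
      exact <- min(sum(st == 1), sum(st == 0)) < 25L
      p <- suppressWarnings(
        stats::wilcox.test(x[st == 1], x[st == 0], exact = exact,
                           correct = TRUE)$p.value)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = nm, level = "median",
        cases = sprintf("%.2f", stats::median(x[st == 1])),
        controls = sprintf("%.2f", stats::median(x[st == 0])),
        p_value = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("descriptive_summary", "data.frame")
  out
}

default_summary_variables <- function(dataset) {
  vars <- list(
    sex = list(kind = "categorical", source = "phenotype", column = "sex"),
    age = list(kind = "continuous", source = "phenotype", column = "age"),
    smoking_status = list(kind = "categorical", source = "phenotype",
                          column = "smoking_status"),
    family_history = list(kind = "categorical", source = "phenotype",
                          column = "family_history"))
  if (!is.null(dataset$nutrients))
    for (nu in names(dataset$nutrients))
      vars[[nu]] <- list(kind = "nutrient", source = "nutrients", column = nu)
  vars
}

#' Chi-square p-value for a contingency table
#'
#' Yates continuity correction for 2x2 tables, plain Pearson otherwise.
#' Identical margins give p = 1.
#'
#' @param tab a contingency table or matrix of counts.
#' @return the p-value.
#' @export
chisq_p <- function(tab) {
  tab <- as.matrix(tab)
  correct <- all(dim(tab) == 2L)
  suppressWarnings(stats::chisq.test(tab, correct = correct)$p.value)
}

#' Crude per-level odds ratios against a reference category
#'
#' From case/control counts by exposure level, the crude odds ratio of each
#' level versus the reference with a Woolf (log-scale normal) 95% confidence
#' interval.
#'
#' @param counts_by_level data.frame or matrix with rows = levels and columns
#'   `cases`, `controls`; row names are the level labels.
#' @param reference_level row name of the reference category.
#' @param conf_level confidence level (default 0.95).
#' @return data.frame (level, or, lower, upper); the reference row has OR 1.
#' @export
categorical_odds_ratios <- function(counts_by_level, reference_level,
                                    conf_level = 0.95) {
  counts <- as.matrix(counts_by_level)
  if (!reference_level %in% rownames(counts))
    stop("reference level '", reference_level, "' not found")
  if (any(counts[reference_level, ] == 0))
    stop("zero cell in the reference level; consider a continuity correction")
  if (any(counts == 0))
    stop("zero cell count; consider adding a continuity correction")
  a_ref <- counts[reference_level, "cases"]
  b_ref <- counts[reference_level, "controls"]
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- do.call(rbind, lapply(rownames(counts), function(lev) {
    a <- counts[lev, "cases"]; b <- counts[lev, "controls"]
    or <- (a * b_ref) / (b * a_ref)
    if (lev == reference_level)
      return(data.frame(level = lev, or = 1, lower = NA_real_,
                        upper = NA_real_, stringsAsFactors = FALSE))
    se <- sqrt(1 / a + 1 / b + 1 / a_ref + 1 / b_ref)
    data.frame(level = lev, or = or, lower = exp(log(or) - z * se),
               upper = exp(log(or) + z * se), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
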