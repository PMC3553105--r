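#' Energy-adjust nutrient intakes (residual method)
#'
#' Replaces each nutrient (energy and alcohol excluded) with its residual
#' from a least-squares regression on total energy intake, plus the predicted
#' intake at the sample-mean energy, so adjusted values stay on the original
#' intake scale. Subjects missing a nutrient are dropped from that nutrient's
#' regression only; their adjusted value is `NA`.
#'
#' @param nutrients a nutrient data.frame (row names subject ids, `energy`
#'   column present) or a [cohort_dataset()].
#' @return the same type of object with adjusted nutrient columns; the
#'   attribute `"energy_adjusted"` names the adjusted columns.
#' @export
energy_adjust <- function(nutrients) {
  is_ds <- inherits(nutrients, "cohort_dataset")
  nut <- if (is_ds) nutrients$nutrients else nutrients
  if (is.null(nut) || !"energy" %in% names(nut))
    stop("nutrient table lacks an energy column")
  if (nrow(nut) < 3L) stop("need at least 3 subjects for energy adjustment")
  energy <- nut$energy
  if (stats::var(energy, na.rm = TRUE) == 0)
    stop("energy intake has zero variance; cannot adjust")
  adjust_cols <- setdiff(names(nut), c("energy", "alcohol"))
  mean_energy <- mean(energy, na.rm = TRUE)
  for (v in adjust_cols) {
    ok <- !is.na(nut[[v]]) & !is.na(energy)
    fit <- stats::lm.fit(cbind(1, energy[ok]), nut[[v]][ok])
    pred_at_mean <- sum(fit$coefficients * c(1, mean_energy))
    adj <- rep(NA_real_, nrow(nut))
    adj[ok] <- fit$residuals + pred_at_mean
    nut[[v]] <- adj
  }
  attr(nut, "energy_adjusted") <- adjust_cols
  if (is_ds) { nutrients$nutrients <- nut; nutrients } else nut
}

#' Categorize alcohol intake
#'
#' Dichotomizes daily alcohol intake into non-drinker (exactly 0 g/day)
#' versus drinker, and bins it into five consumption levels:
#' nondrinker, 0.1-4.9, 5.0-14.9, 15-29.9, and >30 g/day. The interval
#' boundaries are closed as \[0\], (0,5), \[5,15), \[15,30), \[30,Inf) so the
#' category labels leave no gaps.
#'
#' @param g_per_day numeric vector of daily intakes (g); `NA` passed through.
#' @return list with factors `binary` (levels nondrinker, drinker) and
#'   `five_level`.
#' @export
categorize_alcohol <- function(g_per_day) {
  if (any(g_per_day < 0, na.rm = TRUE)) stop("negative alcohol intake")
  binary <- factor(ifelse(g_per_day > 0, "drinker", "nondrinker"),
                   levels = c("nondrinker", "drinker"))
  labels <- c("nondrinker", "0.1-4.9 g/day", "5.0-14.9 g/day",
              "15-29.9 g/day", ">30 g/day")
  idx <- findInterval(g_per_day, c(5, 15, 30)) + 2L
  idx[!is.na(g_per_day) & g_per_day == 0] <- 1L
  five <- factor(labels[idx], levels = labels)
  list(binary = binary, five_level = five)
}
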