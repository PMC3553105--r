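#' Scenario configuration for a synthetic case-control study
#'
#' Fully specifies a simulated cohort: per-smoking-stratum case/control
#' counts, the SNP panel as per-gene LD blocks (minor allele frequencies and
#' within-block target r-squared), the nutrient model (log-normal energy,
#' per-nutrient loading on energy, alcohol zero-mass), true log odds ratios
#' for a few SNP, nutrient and interaction effects, and per-SNP missingness.
#'
#' @param strata named list (`never`, `former`, `current`) of
#'   `c(cases =, controls =)` counts.
#' @param genes data.frame with columns gene, chrom, start, n_snps, maf_min,
#'   maf_max, ld_rho (latent AR decay within the block), spacing (bp).
#' @param nutrients data.frame with columns name, median, loading (log-scale
#'   loading on standardized log energy), sd_log (residual log-sd).
#' @param energy list with `median` (kcal) and `sd_log`.
#' @param alcohol list with `nondrinker_frac`, `median_g` (among drinkers),
#'   `sd_log`.
#' @param effects named numeric vector of true log odds ratios; names are
#'   rsIDs, nutrient names, or `"<nutrient>*<rsid>"` interactions. A special
#'   name `"alcohol"` applies to the drinker indicator.
#' @param intercept baseline log-odds of disease in the source population.
#' @param missingness list with `rate` (per-SNP missing-call probability),
#'   `n_high` (number of SNPs given `high_rate`), `high_rate`.
#' @param oversample source-population multiple of the requested totals used
#'   for retrospective sampling (default 20).
#' @param seed RNG seed.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(strata, genes, nutrients, energy, alcohol,
                            effects = numeric(0), intercept = -1,
                            missingness = list(rate = 0.01, n_high = 0,
                                               high_rate = 0.12),
                            oversample = 20, seed = 1) {
  stopifnot(all(c("never", "former", "current") %in% names(strata)))
  for (s in strata) stopifnot(all(s > 0))
  stopifnot(all(genes$maf_min > 0.01), all(genes$maf_max <= 0.5),
            all(genes$ld_rho >= 0), all(genes$ld_rho < 1))
  structure(list(strata = strata, genes = genes, nutrients = nutrients,
                 energy = energy, alcohol = alcohol, effects = effects,
                 intercept = intercept, missingness = missingness,
                 oversample = oversample, seed = seed),
            class = "scenario_config")
}

#' Bundled demonstration scenario
#'
#' A study-shaped scenario: six folate-pathway gene blocks totalling 115
#' SNPs, 15 energy-correlated nutrients with intake medians near those of a
#' typical food-frequency cohort, smoking-stratum sizes of 316/427 (never),
#' 453/266 (former) and 406/357 (current) cases/controls, and a handful of
#' planted SNP, nutrient and SNP-by-nutrient effects with per-allele log
#' odds ratios around |0.7| (odds ratios near 2 or 1/2).
#'
#' @param seed RNG seed.
#' @param n_snps total SNP panel size (default 115; reduce for quick runs).
#' @param strata optionally override the stratum sizes.
#' @return a [scenario_config()].
#' @export
demo_scenario <- function(seed = 7, n_snps = 115, strata = NULL) {
  genes <- data.frame(
    gene = c("MTHFR", "MTR", "MTRR", "CBS", "SHMT1", "TYMS"),
    chrom = c("1", "1", "5", "21", "17", "18"),
    start = c(11845780, 236958550, 7851190, 43053190, 18231770, 657600),
    n_snps = c(20, 15, 35, 20, 10, 15),
    maf_min = c(0.08, 0.10, 0.05, 0.10, 0.12, 0.08),
    maf_max = c(0.45, 0.40, 0.50, 0.45, 0.40, 0.45),
    ld_rho = c(0.55, 0.50, 0.60, 0.55, 0.45, 0.50),
    spacing = c(9000, 12000, 11000, 9000, 15000, 10000),
    stringsAsFactors = FALSE)
  stopifnot(n_snps >= 20)
  if (n_snps != 115) {
    prop <- genes$n_snps / sum(genes$n_snps)
    genes$n_snps <- pmax(2L, round(prop * n_snps))
  }
  nutrients <- data.frame(
    name = c("carbohydrate", "protein", "total_fat", "betaine", "choline",
             "folate", "methionine", "niacin", "pantothenic_acid",
             "riboflavin", "thiamin", "vitamin_b6", "vitamin_b12",
             "vitamin_c"),
    median = c(232, 76, 68, 53, 143, 514, 1555, 22.7, 5.3, 2.2, 1.5, 2.1,
               5.4, 90),
    loading = c(0.9, 0.8, 0.85, 0.4, 0.5, 0.45, 0.7, 0.6, 0.55, 0.6, 0.6,
                0.5, 0.4, 0.3),
    sd_log = c(0.18, 0.2, 0.22, 0.35, 0.3, 0.33, 0.25, 0.25, 0.25, 0.25,
               0.25, 0.3, 0.4, 0.6),
    stringsAsFactors = FALSE)
  if (is.null(strata))
    strata <- list(never = c(cases = 316, controls = 427),
                   former = c(cases = 453, controls = 266),
                   current = c(cases = 406, controls = 357))
  snp <- function(gene, k) {
    i <- match(gene, genes$gene)
    sprintf("rs%s%03d", i, min(k, genes$n_snps[i]))
  }
  effects <- c(0.74, -0.69, 0.53, -0.64, -0.5)
  names(effects) <- c(snp("MTRR", 5), snp("MTRR", 20), snp("MTHFR", 8),
                      "alcohol", paste0("betaine*", snp("TYMS", 4)))
  scenario_config(
    strata = strata, genes = genes, nutrients = nutrients,
    energy = list(median = 1725, sd_log = 0.35),
    alcohol = list(nondrinker_frac = 0.35, median_g = 6, sd_log = 1.1),
    effects = effects, intercept = -0.6,
    missingness = list(rate = 0.001, n_high = 3, high_rate = 0.12),
    seed = seed)
}

#' Simulate genotypes with block LD structure
#'
#' Per-haplotype latent-Gaussian copula: each subject carries two
#' independent latent Gaussian vectors (one per chromosome copy) with the
#' block's latent correlation; each is thresholded at the allele frequency
#' quantile to an allele indicator, and the genotype is their sum. Genotype
#' frequencies therefore follow Hardy-Weinberg proportions exactly at the
#' stated minor allele frequencies, and the genotype correlation of a pair
#' equals its allele-indicator correlation.
#'
#' @param n subjects.
#' @param blocks list of blocks, each a list with `rsids`, `mafs`, and
#'   either `latent` (latent correlation matrix) or `target_r2` (matrix of
#'   target genotype r-squared, calibrated via [calibrate_latent_corr()]) or
#'   `ld_rho` (latent AR(1) decay).
#' @return numeric genotype matrix (n x total SNPs) of 0/1/2 codes.
#' @export
simulate_genotypes <- function(n, blocks) {
  out <- list()
  for (b in blocks) {
    k <- length(b$rsids)
    stopifnot(length(b$mafs) == k)
    L <- if (!is.null(b$latent)) b$latent
         else if (!is.null(b$target_r2))
           calibrate_latent_block(b$target_r2, b$mafs)
         else b$ld_rho^abs(outer(seq_len(k), seq_len(k), "-"))
    ev <- eigen((L + t(L)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-8) {
      L <- repair_correlation(L)
      if (min(eigen(L, symmetric = TRUE,
                    only.values = TRUE)$values) < 1e-10)
        stop("infeasible latent correlation for block ",
             paste(utils::head(b$rsids, 1)))
    }
    U <- chol(L)
    thr <- stats::qnorm(b$mafs)
    hap <- function() {
      z <- matrix(stats::rnorm(n * k), n, k) %*% U
      sweep(z, 2L, thr, "<") * 1
    }
    out[[length(out) + 1L]] <- hap() + hap()
  }
  g <- do.call(cbind, out)
  colnames(g) <- unlist(lapply(blocks, `[[`, "rsids"))
  g
}

#' Latent correlation achieving a target genotype r-squared
#'
#' For a pair of SNPs with the given minor allele frequencies, finds the
#' latent Gaussian correlation under which the thresholded allele indicators
#' have squared correlation equal to `target_r2` (allele and genotype
#' correlation coincide under the per-haplotype construction). The orthant
#' probability uses one-dimensional numerical integration of the
#' conditional normal CDF.
#'
#' @param target_r2 target squared correlation in \[0, 1).
#' @param maf1,maf2 minor allele frequencies.
#' @return the latent correlation.
#' @export
calibrate_latent_corr <- function(target_r2, maf1, maf2) {
  stopifnot(target_r2 >= 0, target_r2 < 1)
  if (target_r2 == 0) return(0)
  target_r <- sqrt(target_r2)
  f <- function(rho) allele_corr(rho, maf1, maf2) - target_r
  upper <- 0.999999
  if (f(upper) < 0)
    stop("target r2 ", target_r2, " infeasible for MAFs ", maf1, ", ", maf2)
  stats::uniroot(f, c(0, upper), tol = 1e-8)$root
}

allele_corr <- function(rho, maf1, maf2) {
  q1 <- stats::qnorm(maf1); q2 <- stats::qnorm(maf2)
  p11 <- binorm_cdf(q1, q2, rho)
  (p11 - maf1 * maf2) /
    sqrt(maf1 * (1 - maf1) * maf2 * (1 - maf2))
}

# P(X < a, Y < b) under standard bivariate normal with correlation rho
binorm_cdf <- function(a, b, rho) {
  if (abs(rho) < 1e-12) return(stats::pnorm(a) * stats::pnorm(b))
  f <- function(z) stats::pnorm((b - rho * z) / sqrt(1 - rho^2)) *
    stats::dnorm(z)
  stats::integrate(f, -Inf, a, rel.tol = 1e-10)$value
}

calibrate_latent_block <- function(target_r2, mafs) {
  k <- length(mafs)
  L <- diag(k)
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    L[i, j] <- L[j, i] <- calibrate_latent_corr(target_r2[i, j],
                                                mafs[i], mafs[j])
  }
  L
}

#' Simulate energy-correlated nutrient intakes
#'
#' Energy is log-normal around its configured median. Each nutrient is
#' log-normal with its log driven by the standardized log energy times a
#' loading plus independent noise, scaled to the configured median. Alcohol
#' has a point mass at zero (non-drinkers) and a log-normal positive part.
#'
#' @param n subjects.
#' @param nutrient_model data.frame (name, median, loading, sd_log) as in
#'   [scenario_config()].
#' @param energy list(median, sd_log).
#' @param alcohol list(nondrinker_frac, median_g, sd_log).
#' @return nutrient data.frame (energy, alcohol, then the nutrients).
#' @export
simulate_nutrients <- function(n, nutrient_model, energy, alcohol) {
  z_e <- stats::rnorm(n)
  e <- energy$median * exp(energy$sd_log * z_e)
  out <- data.frame(energy = e)
  drink <- stats::runif(n) >= alcohol$nondrinker_frac
  alc <- numeric(n)
  alc[drink] <- alcohol$median_g * exp(alcohol$sd_log *
                                         stats::rnorm(sum(drink)))
  out$alcohol <- alc
  for (i in seq_len(nrow(nutrient_model))) {
    nm <- nutrient_model[i, ]
    lg <- nm$loading * z_e + nm$sd_log * stats::rnorm(n)
    out[[nm$name]] <- nm$median * exp(lg)
  }
  out
}

#' Retrospective case-control phenotype simulation
#'
#' Oversamples a source population under the logistic disease model
#' P(case | x) = plogis(intercept + x' beta_true), then draws exactly the
#' requested numbers of cases and controls. This makes the sampled odds
#' ratios estimate the population odds ratios exactly, as in a
#' frequency-matched case-control design.
#'
#' @param design numeric matrix of risk-factor columns for the source
#'   population (column names matched against `effects`).
#' @param effects named log odds ratios (names must be columns of `design`).
#' @param intercept baseline log-odds.
#' @param n_cases,n_controls required counts.
#' @return list with `rows` (indices into the source population, cases
#'   first) and `case_status`.
#' @export
simulate_phenotype <- function(design, effects, intercept, n_cases,
                               n_controls) {
  miss <- setdiff(names(effects), colnames(design))
  if (length(miss)) stop("effects reference missing columns: ",
                         paste(miss, collapse = ", "))
  eta <- rep(intercept, nrow(design))
  for (nm in names(effects))
    eta <- eta + design[, nm] * effects[[nm]]
  case <- stats::runif(nrow(design)) < stats::plogis(eta)
  if (sum(case) < n_cases || sum(!case) < n_controls)
    stop("source population too small for requested counts; ",
         "increase the oversample factor")
  rows <- c(sample(which(case), n_cases), sample(which(!case), n_controls))
  list(rows = rows,
       case_status = rep(c(1, 0), c(n_cases, n_controls)))
}

#' Inject missing genotype calls
#'
#' Missing completely at random within configured groups: per-SNP missing
#' probabilities, optionally multiplied per subject group (e.g. smoking
#' stratum) to emulate stratum-dependent missingness.
#'
#' @param genotypes genotype matrix.
#' @param rates per-SNP missing probabilities (recycled).
#' @param group_multiplier optional numeric vector (one per subject)
#'   multiplying the rate.
#' @return the matrix with `NA`s injected.
#' @export
inject_missingness <- function(genotypes, rates, group_multiplier = NULL) {
  rates <- rep_len(rates, ncol(genotypes))
  stopifnot(all(rates >= 0 & rates < 1))
  if (is.null(group_multiplier))
    group_multiplier <- rep(1, nrow(genotypes))
  for (j in seq_len(ncol(genotypes))) {
    pr <- pmin(rates[j] * group_multiplier, 0.99)
    miss <- stats::runif(nrow(genotypes)) < pr
    genotypes[miss, j] <- NA
  }
  genotypes
}

#' Generate a complete synthetic study
#'
#' Draws the source population (genotypes with block LD, nutrients,
#' demographic covariates), applies the logistic disease model with the
#' scenario's true effects, samples the configured numbers of cases and
#' controls per smoking stratum, injects genotype missingness, and decodes
#' genotypes to allele-pair calls so the result is schema-identical to a
#' freshly ingested cohort. A truth record carries the planted effects for
#' scoring.
#'
#' @param scenario a [scenario_config()].
#' @return list with `dataset` (a raw-call [cohort_dataset()]) and `truth`
#'   (list: effects, annotation of planted SNPs, per-stratum counts, seed).
#' @export
generate_study <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_config"))
  set.seed(scenario$seed)
  genes <- scenario$genes
  blocks <- list(); ann <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    k <- g$n_snps
    rsids <- sprintf("rs%d%03d", i, seq_len(k))
    mafs <- seq(g$maf_min, g$maf_max, length.out = k)
    blocks[[i]] <- list(rsids = rsids, mafs = mafs, ld_rho = g$ld_rho)
    ann[[i]] <- data.frame(
      rsid = rsids, chrom = g$chrom,
      pos = g$start + g$spacing * (seq_len(k) - 1L), gene = g$gene,
      priority = seq_len(k) %% 7 == 3, stringsAsFactors = FALSE)
  }
  annotation <- do.call(rbind, ann)

  per_smoke <- lapply(names(scenario$strata), function(stratum) {
    counts <- scenario$strata[[stratum]]
    n_src <- ceiling(scenario$oversample * sum(counts))
    geno <- simulate_genotypes(n_src, blocks)
    nut <- simulate_nutrients(n_src, scenario$nutrients, scenario$energy,
                              scenario$alcohol)
    X <- cbind(geno, as.matrix(nut))
    X <- cbind(X, alcohol_drinker = as.numeric(nut$alcohol > 0))
    eff <- scenario$effects
    names(eff)[names(eff) == "alcohol"] <- "alcohol_drinker"
    for (nm in names(eff)) {
      if (grepl("\\*", nm) && !nm %in% colnames(X)) {
        parts <- strsplit(nm, "\\*")[[1L]]
        nu <- parts[1L]; sn <- parts[2L]
        zc <- drop(scale(log(pmax(X[, nu], 1e-8))))
        X <- cbind(X, newcol = zc * X[, sn])
        colnames(X)[ncol(X)] <- nm
      }
    }
    ph <- simulate_phenotype(X, eff, scenario$intercept,
                             counts["cases"], counts["controls"])
    rows <- ph$rows
    list(stratum = stratum, geno = geno[rows, , drop = FALSE],
         nut = nut[rows, , drop = FALSE], case_status = ph$case_status)
  })

  geno <- do.call(rbind, lapply(per_smoke, `[[`, "geno"))
  nut <- do.call(rbind, lapply(per_smoke, `[[`, "nut"))
  status <- unlist(lapply(per_smoke, `[[`, "case_status"))
  smoking <- rep(names(scenario$strata),
                 vapply(per_smoke, function(x) length(x$case_status),
                        numeric(1)))
  n <- length(status)
  ids <- sprintf("S%05d", seq_len(n))
  rownames(geno) <- ids
  rownames(nut) <- ids

  pheno <- data.frame(
    subject_id = ids, case_status = status,
    sex = sample(c("male", "female"), n, replace = TRUE),
    age = round(stats::rnorm(n, 60, 10), 1),
    family_history = stats::rbinom(n, 1, 0.25),
    smoking_status = smoking,
    pack_years = NA_real_, cessation_age = NA_real_,
    ets_exposed = NA_real_, stringsAsFactors = FALSE)
  smoker <- smoking != "never"
  pheno$pack_years[smoker] <- round(stats::rgamma(sum(smoker), shape = 2,
                                                  scale = 25), 1)
  former <- smoking == "former"
  pheno$cessation_age[former] <- round(stats::runif(sum(former), 30, 65))
  nf <- smoking %in% c("never", "former")
  pheno$ets_exposed[nf] <- stats::rbinom(sum(nf), 1, 0.6)

  # stratum-dependent missingness: smokers get a higher rate
  mi <- scenario$missingness
  rates <- rep(mi$rate, ncol(geno))
  if (mi$n_high > 0)
    rates[sample.int(ncol(geno), mi$n_high)] <- mi$high_rate
  mult <- ifelse(smoking == "current", 1.5, 1)
  geno <- inject_missingness(geno, rates, mult)

  raw <- decode_genotypes(geno, annotation)
  dataset <- cohort_dataset(raw, annotation, pheno, nut)
  truth <- list(effects = scenario$effects, annotation = annotation,
                strata = scenario$strata, seed = scenario$seed,
                missing_rates = stats::setNames(rates, colnames(geno)))
  list(dataset = dataset, truth = truth)
}

# deterministic allele-pair decoding of 0/1/2 codes (ref/alt per SNP cycle)
decode_genotypes <- function(geno, annotation) {
  pairs <- matrix(c("A", "G", "C", "T", "A", "C", "G", "T"), ncol = 2,
                  byrow = TRUE)
  raw <- matrix(NA_character_, nrow(geno), ncol(geno),
                dimnames = dimnames(geno))
  for (j in seq_len(ncol(geno))) {
    al <- pairs[(j - 1L) %% nrow(pairs) + 1L, ]
    code <- geno[, j]
    raw[, j] <- c(paste0(al[1], al[1]), paste0(al[1], al[2]),
                  paste0(al[2], al[2]))[code + 1L]
  }
  raw
}
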