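test_that("read_cohort round-trips aligned fixture files", {
  paths <- write_tiny_cohort()
  ds <- read_cohort(paths["genotypes"], paths["annotation"],
                    paths["phenotype"], paths["nutrients"])
  expect_s3_class(ds, "cohort_dataset")
  expect_identical(rownames(ds$genotypes), c("s1", "s2"))
  expect_identical(ds$phenotype$subject_id, c("s1", "s2"))
  expect_identical(rownames(ds$nutrients), c("s1", "s2"))
  expect_false(ds$encoded)
})

test_that("subjects not in every file are dropped with a warning", {
  paths <- write_tiny_cohort(extra_pheno_subject = "s3")
  expect_warning(
    ds <- read_cohort(paths["genotypes"], paths["annotation"],
                      paths["phenotype"], paths["nutrients"]),
    "s3")
  expect_identical(ds$phenotype$subject_id, c("s1", "s2"))
})

test_that("allele outside the annotated pair errors naming the SNP", {
  paths <- write_tiny_cohort(bad_call = "AT")
  expect_error(
    read_cohort(paths["genotypes"], paths["annotation"],
                paths["phenotype"], paths["nutrients"]),
    "rs1")
})

test_that("PLINK-style ped/map dialect reads identically", {
  dir <- withr::local_tempdir()
  # map: chrom rsid cm pos
  write.table(data.frame(c("1", "1"), c("rs1", "rs2"), c(0, 0),
                         c(1000L, 2000L)),
              file.path(dir, "g.map"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  writeLines(c("F1 s1 0 0 1 2 A A C C",
               "F2 s2 0 0 2 1 A G 0 0"), file.path(dir, "g.ped"))
  paths <- write_tiny_cohort(dir)
  ds <- read_cohort(file.path(dir, "g.ped"), paths["annotation"],
                    paths["phenotype"], paths["nutrients"],
                    format_dialect = "ped")
  expect_identical(unname(ds$genotypes["s1", ]), c("AA", "CC"))
  expect_true(is.na(ds$genotypes["s2", "rs2"]))
})

test_that("additive encoding counts minor alleles with major homozygote 0", {
  g <- matrix(c("AA", "AA", "AG", "GG"), 4, 1,
              dimnames = list(NULL, "rs1"))
  ds <- make_dataset(g, status = c(1, 0, 1, 0))
  enc <- encode_additive(ds)
  # freq(G) = 3/8 -> G minor
  expect_equal(unname(enc$genotypes[, 1]), c(0, 0, 1, 2))
  expect_identical(enc$encoding$major, "A")
  # heterozygote order-invariant
  g2 <- matrix(c("AA", "AA", "GA", "GG"), 4, 1,
               dimnames = list(NULL, "rs1"))
  enc2 <- encode_additive(make_dataset(g2, status = c(1, 0, 1, 0)))
  expect_equal(enc$genotypes, enc2$genotypes, ignore_attr = TRUE)
})

test_that("50/50 allele ties pick the lexicographically smaller reference", {
  g <- matrix(c("AG", "GA", "AA", "GG"), 4, 1,
              dimnames = list(NULL, "rs1"))
  enc <- encode_additive(make_dataset(g, status = c(1, 0, 1, 0)))
  expect_identical(enc$encoding$major, "A")
  expect_equal(unname(enc$genotypes[, 1]), c(1, 1, 0, 2))
})

test_that("monomorphic SNPs encode all-zero with a warning", {
  g <- cbind(rs1 = rep("AA", 4), rs2 = c("CT", "CC", "TT", "CT"))
  expect_warning(enc <- encode_additive(make_dataset(g, c(1, 0, 1, 0))),
                 "monomorphic")
  expect_true(all(enc$genotypes[, "rs1"] == 0))
})

test_that("encoded column sums equal twice the minor-homozygote count plus hets", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 40
    calls <- replicate(3, {
      al <- sample(c("A", "G"), 2)
      paste0(sample(al, n, TRUE, prob = c(.7, .3)),
             sample(al, n, TRUE, prob = c(.7, .3)))
    })
    colnames(calls) <- paste0("rs", 1:3)
    enc <- suppressWarnings(
      encode_additive(make_dataset(calls, rep(0:1, 20))))
    g <- enc$genotypes
    for (j in 1:3) {
      minor <- enc$encoding$minor[j]
      if (is.na(minor)) next
      n_minor <- sum(vapply(strsplit(calls[, j], ""),
                            function(a) sum(a == minor), numeric(1)))
      expect_equal(sum(g[, j]), n_minor)
      expect_lte(mean(g[, j]) / 2, 0.5 + 1e-12)  # minor allele freq <= .5
    }
  }
})

test_that("QC filter removes SNPs violating any rule and reports reasons", {
  set.seed(2)
  n <- 100
  g <- matrix(sample(0:2, n * 3, TRUE), n, 3,
              dimnames = list(NULL, c("ok", "miss11", "rare")))
  g[1:11, "miss11"] <- NA                     # 11% missing
  g[, "rare"] <- c(1, rep(0, n - 1))          # MAF 0.005
  ds <- make_dataset(g, rep(0:1, 50))
  out <- qc_filter_snps(ds)
  rep_tab <- out$report
  expect_true(grepl("missing_max", rep_tab$reason[rep_tab$rsid == "miss11"]))
  expect_true(grepl("maf", rep_tab$reason[rep_tab$rsid == "rare"]))
  expect_identical(colnames(out$dataset$genotypes), "ok")
  expect_equal(attr(rep_tab, "n_removed") + attr(rep_tab, "n_retained"),
               ncol(g))
  # idempotence
  out2 <- qc_filter_snps(out$dataset)
  expect_identical(out2$dataset$genotypes, out$dataset$genotypes)
  expect_equal(attr(out2$report, "n_removed"), 0L)
})

test_that("MAF is computed by allele counting (4 AA, 1 AG -> 0.1, retained)", {
  g <- matrix(c("AA", "AA", "AA", "AA", "AG"), 5, 1,
              dimnames = list(NULL, "rs1"))
  ds <- make_dataset(g, c(1, 0, 1, 0, 1))
  out <- qc_filter_snps(ds)
  expect_equal(out$report$maf, 0.1)
  expect_false(out$report$removed)
})

test_that("a planted panel with 39 violating SNPs keeps the rest", {
  set.seed(31)
  n <- 400
  n_snp <- 293
  g <- matrix(rbinom(n * n_snp, 2, 0.3), n, n_snp,
              dimnames = list(NULL, sprintf("rs%03d", 1:n_snp)))
  bad <- sample(n_snp, 39)
  kinds <- rep_len(c("missing", "rare"), 39)
  for (k in seq_along(bad)) {
    j <- bad[k]
    if (kinds[k] == "missing") g[sample(n, ceiling(0.12 * n)), j] <- NA
    else g[, j] <- rbinom(n, 2, 0.004)
  }
  ds <- make_dataset(g, rep(0:1, n / 2))
  out <- qc_filter_snps(ds)
  expect_equal(attr(out$report, "n_removed"), 39L)
  expect_equal(ncol(out$dataset$genotypes), 254L)
})

test_that("missingness-status independence test is calibrated and powered", {
  set.seed(7)
  n <- 2000
  status <- rep(0:1, each = n / 2)
  g <- matrix(sample(0:2, n * 200, TRUE), n, 200,
              dimnames = list(NULL, sprintf("rs%03d", 1:200)))
  miss <- matrix(runif(n * 200) < 0.05, n, 200)   # MCAR
  g[miss] <- NA
  ds <- make_dataset(g, status)
  res <- missingness_independence_test(ds)
  expect_true(abs(mean(res$p_value < 0.05) - 0.05) < 0.04)
  # missing only in cases -> strongly significant
  g2 <- cbind(rs1 = sample(0:2, n, TRUE))
  g2[sample(which(status == 1), 20), 1] <- NA
  res2 <- missingness_independence_test(make_dataset(g2, status))
  expect_lt(res2$p_value, 0.001)
  # no missing -> NA marker
  g3 <- cbind(rs1 = sample(0:2, 50, TRUE))
  res3 <- missingness_independence_test(make_dataset(g3, rep(0:1, 25)))
  expect_true(is.na(res3$p_value))
})

test_that("complete-case filter keeps exactly the fully observed subjects", {
  g <- matrix(c(0, 1, NA, 2, 1, 0, 1, 2), 4, 2,
              dimnames = list(NULL, c("rs1", "rs2")))
  ds <- make_dataset(g, c(1, 1, 0, 0))
  out <- suppressMessages(complete_case_filter(ds))
  expect_equal(nrow(out$genotypes), 3L)
  cc <- attr(out, "complete_case_counts")
  expect_equal(unname(cc["controls_dropped"]), 1)
  # no missing -> identity
  ds2 <- make_dataset(g[c(1, 2, 4), , drop = FALSE], c(1, 1, 0))
  out2 <- suppressMessages(complete_case_filter(ds2))
  expect_equal(nrow(out2$genotypes), 3L)
  expect_error(complete_case_filter(ds, character(0)), "nonempty")
})
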