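# Shared fixtures, all generated in code.

# Write a tiny aligned trio (+nutrients) of cohort files; returns the paths.
write_tiny_cohort <- function(dir = NULL, extra_pheno_subject = NULL,
                              bad_call = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("cohort")
    dir.create(dir)
  }
  geno <- data.frame(subject_id = c("s1", "s2"),
                     rs1 = c("AA", "AG"), rs2 = c("CC", "CT"),
                     stringsAsFactors = FALSE)
  if (!is.null(bad_call)) geno$rs1[2] <- bad_call
  ann <- data.frame(rsid = c("rs1", "rs2"), chrom = c("1", "1"),
                    pos = c(1000L, 2000L), gene = c("G1", "G1"),
                    priority = c(FALSE, TRUE), alleles = c("A/G", "C/T"),
                    stringsAsFactors = FALSE)
  ph <- data.frame(subject_id = c("s1", "s2"), case_status = c(1L, 0L),
                   sex = c("male", "female"), age = c(60, 55),
                   family_history = c(0L, 1L),
                   smoking_status = c("never", "current"),
                   pack_years = c(NA, 30), cessation_age = c(NA, NA),
                   ets_exposed = c(1L, NA), stringsAsFactors = FALSE)
  if (!is.null(extra_pheno_subject))
    ph <- rbind(ph, data.frame(subject_id = extra_pheno_subject,
                               case_status = 0L, sex = "male", age = 50,
                               family_history = 0L,
                               smoking_status = "never", pack_years = NA,
                               cessation_age = NA, ets_exposed = 0L))
  nut <- data.frame(subject_id = c("s1", "s2"), energy = c(1800, 2100),
                    alcohol = c(0, 12), folate = c(400, 520))
  paths <- c(genotypes = file.path(dir, "geno.tsv"),
             annotation = file.path(dir, "ann.tsv"),
             phenotype = file.path(dir, "pheno.csv"),
             nutrients = file.path(dir, "nut.csv"))
  write.table(geno, paths["genotypes"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(ann, paths["annotation"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.csv(ph, paths["phenotype"], row.names = FALSE)
  write.csv(nut, paths["nutrients"], row.names = FALSE)
  paths
}

# Encoded in-memory dataset with configurable genotypes/status.
make_dataset <- function(geno, status, smoking = NULL, nutrients = NULL,
                         annotation = NULL) {
  n <- nrow(geno)
  ids <- sprintf("s%03d", seq_len(n))
  rownames(geno) <- ids
  if (is.null(annotation))
    annotation <- data.frame(rsid = colnames(geno), chrom = "1",
                             pos = seq_len(ncol(geno)) * 1000L,
                             gene = "G1", priority = FALSE,
                             stringsAsFactors = FALSE)
  if (is.null(smoking)) smoking <- rep("never", n)
  ph <- data.frame(subject_id = ids, case_status = status,
                   sex = rep(c("male", "female"), length.out = n),
                   age = seq(40, 70, length.out = n),
                   family_history = rep(0:1, length.out = n),
                   smoking_status = smoking,
                   pack_years = ifelse(smoking == "never", NA, 30),
                   cessation_age = ifelse(smoking == "former", 45, NA),
                   ets_exposed = ifelse(smoking == "current", NA, 1),
                   stringsAsFactors = FALSE)
  if (!is.null(nutrients)) rownames(nutrients) <- ids
  ds <- cohort_dataset(geno, annotation, ph, nutrients)
  ds
}

# Small quick sampler config for unit tests.
quick_config <- function(n_iter = 4000, n_chains = 2, seed = 1, ...) {
  sampler_config(n_iter = n_iter, n_chains = n_chains, seed = seed, ...)
}
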