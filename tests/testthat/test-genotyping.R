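# Plates, VCF ingestion, dosage matrices, the GRM, and export round trips.

geno_fixture <- function(n = 6) {
  st <- create_store()
  add_accessions(st, data.frame(name = sprintf("S%02d", 1:n),
                                species = "Manihot esculenta"))
  st
}

test_that("plates fill row-major with valid well ids and capacities", {
  st <- geno_fixture(3)
  p <- create_plate(st, "PL1", 96, c("S01", "S02", "S03"))
  expect_equal(names(p$wells), c("A01", "A02", "A03"))
  expect_equal(unname(p$wells), c("S01", "S02", "S03"))
  # 96-well grammar: rows A-H, columns 01-12
  st2 <- geno_fixture(3)
  full <- create_plate(st2, "FULL", 96, sprintf("X%03d", 1:96))
  expect_length(full$wells, 96)
  expect_true(all(grepl("^[A-H](0[1-9]|1[0-2])$", names(full$wells))))
  expect_equal(names(full$wells)[13], "B01")  # row-major wrap
  expect_error(create_plate(st2, "OVER", 96, sprintf("Y%03d", 1:97)),
               class = "bb_capacity_exceeded")
  # 384 = 16 x 24, rows A-P
  big <- create_plate(st2, "BIG", 384, sprintf("Z%03d", 1:384))
  expect_length(big$wells, 384)
  expect_true(all(grepl("^[A-P](0[1-9]|1[0-9]|2[0-4])$", names(big$wells))))
  expect_error(create_plate(st2, "DUP", 96, c("a", "a")),
               class = "bb_duplicate_sample")
  expect_error(create_plate(st2, "BADF", 48, "a"), class = "bb_bad_format")
})

test_that("VCF loading counts ALT alleles, skips non-biallelic, maps samples", {
  st <- geno_fixture(2)
  f <- tempfile(fileext = ".vcf")
  write_test_vcf(f, samples = c("S01", "vcfname2"),
                 chrom = c("1", "1", "1", "2"), pos = c(100, 200, 300, 50),
                 id = c("m1", "m2", "m3", "m4"),
                 ref = c("A", "C", "G", "AT"), alt = c("T", "G,A", "A", "C"),
                 gt = rbind(c("0/0", "0/1"), c("1/1", "0/0"),
                            c("1/1", "./."), c("0/1", "0/0")))
  rep <- load_vcf(st, f, "GBSv1", sample_map = c(vcfname2 = "S02"))
  expect_equal(rep$markers_added, 2)    # m2 multi-allelic, m4 non-SNP
  expect_equal(rep$records_skipped, 2)
  expect_setequal(rep$samples_stored, c("S01", "S02"))
  dm <- dosage_matrix(st, "GBSv1")
  expect_equal(unname(dm$X["S01", c("m1", "m3")]), c(0, 2))
  expect_equal(unname(dm$X["S02", "m1"]), 1)
  expect_true(is.na(dm$X["S02", "m3"]))

  # unmatched samples are reported, not stored
  st2 <- geno_fixture(1)
  f2 <- tempfile(fileext = ".vcf")
  write_test_vcf(f2, samples = c("S01", "STRANGER"),
                 chrom = "1", pos = 1, id = "m1", ref = "A", alt = "C",
                 gt = rbind(c("0/1", "1/1")))
  rep2 <- load_vcf(st2, f2, "P2")
  expect_equal(rep2$unmatched, "STRANGER")
  expect_equal(rep2$samples_stored, "S01")
})

test_that("polyploid GT dosages are ALT counts with missing propagation", {
  st <- geno_fixture(2)
  f <- tempfile(fileext = ".vcf")
  write_test_vcf(f, samples = c("S01", "S02"),
                 chrom = "1", pos = c(10, 20), id = c("m1", "m2"),
                 ref = c("A", "A"), alt = c("T", "T"),
                 gt = rbind(c("0/1/1", "1/1/1"), c("0/./1", "0|1|0")))
  rep <- load_vcf(st, f, "TRIP", ploidy = 3)
  dm <- dosage_matrix(st, "TRIP")
  expect_equal(unname(dm$X["S01", ]), c(2, NA))
  expect_equal(unname(dm$X["S02", ]), c(3, 1))
  expect_error(export_vcf(st, "TRIP", tempfile()), class = "bb_bad_ploidy")
})

test_that("dosage matrix imputation and frequencies follow the column rules", {
  st <- geno_fixture(3)
  scores <- rbind(S01 = c(m1 = 0, m2 = 0, m3 = NA),
                  S02 = c(m1 = 2, m2 = 0, m3 = NA),
                  S03 = c(m1 = NA, m2 = 0, m3 = NA))
  add_genotypes(st, "P", scores,
                markers = data.frame(name = paste0("m", 1:3), chrom = "1",
                                     pos = 1:3, ref_allele = "A", alt_allele = "T"))
  dm <- dosage_matrix(st, "P", impute = "mean")
  expect_equal(unname(dm$X[, "m1"]), c(0, 2, 1))  # mean of {0,2} fills the gap
  expect_equal(unname(dm$p["m1"]), 0.5)
  expect_equal(dm$monomorphic, "m2")
  expect_equal(dm$dropped, "m3")
  dm0 <- dosage_matrix(st, "P", impute = "none")
  expect_true(is.na(dm0$X["S03", "m1"]))
  # frequency example: column {0,1,2} diploid -> p = 0.5
  st2 <- geno_fixture(3)
  add_genotypes(st2, "P", rbind(S01 = c(m1 = 0), S02 = c(m1 = 1), S03 = c(m1 = 2)),
                markers = data.frame(name = "m1", chrom = "1", pos = 1,
                                     ref_allele = "A", alt_allele = "T"))
  expect_equal(unname(dosage_matrix(st2, "P")$p), 0.5)
})

test_that("the GRM reproduces the worked 2x2 example and a double-loop oracle", {
  X <- rbind(a = c(0, 2), b = c(2, 0))
  G <- compute_grm(X, c(0.5, 0.5))
  expect_equal(unname(G), rbind(c(2, -2), c(-2, 2)))

  set.seed(5)
  Xr <- matrix(rbinom(20 * 50, 2, 0.4), 20, 50,
               dimnames = list(sprintf("i%02d", 1:20), sprintf("m%02d", 1:50)))
  p <- colMeans(Xr) / 2
  G1 <- compute_grm(Xr, p)
  G2 <- grm_oracle(Xr, p)
  expect_lt(max(abs(G1 - G2)), 1e-10)
  expect_equal(G1, t(G1))

  # identical samples give identical rows/diagonal entries
  Xi <- rbind(a = c(0, 1, 2), b = c(0, 1, 2), c = c(2, 1, 0))
  Gi <- compute_grm(Xi, colMeans(Xi) / 2)
  expect_equal(Gi["a", "a"], Gi["b", "b"])
  expect_equal(Gi["a", "c"], Gi["b", "c"])

  # permutation equivariance
  perm <- c(3, 1, 2)
  Gp <- compute_grm(Xi[perm, ], colMeans(Xi) / 2)
  expect_equal(unname(Gp), unname(Gi[perm, perm]))

  # degenerate inputs
  expect_error(compute_grm(rbind(c(0, NA)), c(0.5, 0.5)), class = "bb_missing_values")
  expect_error(compute_grm(rbind(c(0, 0), c(0, 0)), c(0, 0)),
               class = "bb_no_polymorphic_markers")
})

test_that("VCF export round-trips diploid dosages exactly", {
  st <- geno_fixture(4)
  set.seed(9)
  m <- 12
  scores <- matrix(sample(c(0:2, NA), 4 * m, replace = TRUE,
                          prob = c(.3, .3, .3, .1)), 4, m,
                   dimnames = list(sprintf("S%02d", 1:4), sprintf("mk%02d", 1:m)))
  add_genotypes(st, "P", scores,
                markers = data.frame(name = sprintf("mk%02d", 1:m), chrom = "1",
                                     pos = 1:m, ref_allele = "A", alt_allele = "G"))
  f <- tempfile(fileext = ".vcf")
  export_vcf(st, "P", f)
  txt <- readLines(f)
  expect_true(any(grepl("^##fileformat=VCFv4.2", txt)))
  expect_true(any(grepl("\\./\\.", txt)))  # missing renders as ./.

  st2 <- geno_fixture(4)
  load_vcf(st2, f, "P2")
  dm1 <- dosage_matrix(st, "P")
  dm2 <- dosage_matrix(st2, "P2")
  expect_identical(dm1$X[rownames(dm2$X), colnames(dm2$X)], dm2$X)

  # load -> export -> load idempotence
  f2 <- tempfile(fileext = ".vcf")
  export_vcf(st2, "P2", f2)
  expect_identical(readLines(f)[-(1:4)], readLines(f2)[-(1:4)])

  # marker order in the file follows protocol (chrom, pos) order
  body <- txt[!startsWith(txt, "#")]
  pos <- as.integer(vapply(strsplit(body, "\t"), `[[`, character(1), 2))
  expect_identical(pos, sort(pos))
})

test_that("dosage TSV export writes samples x markers with NA for missing", {
  st <- geno_fixture(2)
  add_genotypes(st, "P", rbind(S01 = c(m1 = 0, m2 = NA), S02 = c(m1 = 2, m2 = 1)),
                markers = data.frame(name = c("m1", "m2"), chrom = "1",
                                     pos = 1:2, ref_allele = "A", alt_allele = "T"))
  f <- tempfile(fileext = ".tsv")
  export_dosage_tsv(st, "P", f)
  df <- read.delim(f, check.names = FALSE)
  expect_equal(df$sample, c("S01", "S02"))
  expect_true(is.na(df$m2[1]))
  expect_equal(df$m1, c(0, 2))
})

test_that("stored dosages always respect the ploidy bounds", {
  st <- geno_fixture(1)
  expect_error(add_genotypes(st, "P", rbind(S01 = c(m1 = 3)),
                             markers = data.frame(name = "m1", chrom = "1", pos = 1,
                                                  ref_allele = "A", alt_allele = "T")),
               class = "bb_bad_dosage")
  sim <- simulate_program(n_founders = 10, n_crosses = 2, progeny_per_cross = 2,
                          n_markers = 50, seed = 4)
  geno <- sim$store$genotypes[["SIM-GBS"]]
  expect_true(all(vapply(geno, function(v) all(v >= 0 & v <= 2, na.rm = TRUE),
                         logical(1))))
})
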