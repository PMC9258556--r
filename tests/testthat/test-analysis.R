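# Analyses: summaries, outliers, filtering, correlations, adjusted means,
# heritability, GBLUP, selection index, and result round-tripping.

test_that("trait summaries use sample sd and count missing units", {
  st <- balanced_trial_store(genos = paste0("G", 1:4), reps = 1,
                             geno_eff = c(1, 2, 3, 0) - 10 + 0)
  # overwrite: three observed values {1,2,3} and one unit left unobserved
  un <- trial_units(st, "BAL-T1", "plot")$name
  st$observations <- st$observations[0, ]
  for (i in 1:3) record_observation(st, un[i], "toy trait", as.character(i))
  s <- trait_summary(st, "toy trait", units = un)
  expect_equal(s[c("n", "mean", "sd", "min", "max", "n_missing")],
               list(n = 3L, mean = 2, sd = 1, min = 1, max = 3, n_missing = 1L))
  # constant values: sd 0; single value: sd missing
  for (i in 1:3) record_observation(st, un[i], "toy trait", "5")
  expect_equal(trait_summary(st, "toy trait", units = un[1:3])$sd, 0)
  expect_true(is.na(trait_summary(st, "toy trait", units = un[1])$sd))
  expect_error(trait_summary(st, "toy trait", units = un[4]),
               class = "bb_empty_dataset")
})

test_that("robust z-scores flag gross outliers and tolerate zero MAD", {
  st <- balanced_trial_store(genos = paste0("G", 1:4), reps = 1)
  un <- trial_units(st, "BAL-T1", "plot")$name
  st$observations <- st$observations[0, ]
  vals <- c(10, 11, 12, 100)
  for (i in 1:4) record_observation(st, un[i], "toy trait", as.character(vals[i]))
  fl <- flag_outliers(st, "toy trait", units = un)
  expect_equal(fl$value, 100)
  expect_equal(fl$z, 88.5 / 1.4826, tolerance = 1e-10)
  # flagging never mutates the data
  expect_equal(nrow(st$observations), 4)

  st2 <- balanced_trial_store(genos = paste0("G", 1:4), reps = 1)
  un2 <- trial_units(st2, "BAL-T1", "plot")$name
  st2$observations <- st2$observations[0, ]
  for (i in 1:4) record_observation(st2, un2[i], "toy trait", "5")
  expect_equal(nrow(flag_outliers(st2, "toy trait", units = un2)), 0)
  # symmetric mild data: nothing at threshold 3.5
  for (i in 1:4) record_observation(st2, un2[i], "toy trait",
                                    as.character(c(8, 9, 11, 12)[i]))
  expect_equal(nrow(flag_outliers(st2, "toy trait", units = un2)), 0)
})

test_that("range filters keep in-range units and compose by intersection", {
  st <- balanced_trial_store(genos = paste0("G", 1:3), reps = 1)
  un <- trial_units(st, "BAL-T1", "plot")$name
  st$observations <- st$observations[0, ]
  vals <- c(1, 5, 9)
  for (i in 1:3) record_observation(st, un[i], "toy trait", as.character(vals[i]))
  kept <- filter_by_range(st, "toy trait", units = un, min = 2, max = 8)
  expect_equal(kept, un[2])
  expect_setequal(filter_by_range(st, "toy trait", units = un, min = 0, max = 10), un)
  chained <- filter_by_range(st, "toy trait",
                             units = filter_by_range(st, "toy trait", units = un, min = 2),
                             max = 8)
  both <- filter_by_range(st, "toy trait", units = un, min = 2, max = 8)
  expect_identical(chained, both)
  expect_error(filter_by_range(st, "toy trait", units = un, min = 9, max = 1),
               class = "bb_bad_argument")
  expect_error(filter_by_range(st, "toy trait", units = un),
               class = "bb_bad_argument")
})

test_that("correlation matrices are pairwise-complete with guarded cells", {
  st <- create_store()
  add_breeding_program(st, "P"); add_location(st, "L")
  genos <- sprintf("G%03d", 1:100)
  add_accessions(st, data.frame(name = genos, species = "Zea mays"))
  add_trait_variable(st, "V1", "t1", scale_class = "numeric")
  add_trait_variable(st, "V2", "t2", scale_class = "numeric")
  add_trait_variable(st, "V3", "t3", scale_class = "numeric")
  lay <- new_test_layout(genos, 5)
  create_trial(st, "T", "P", "L", 2020, lay)
  un <- trial_units(st, "T", "plot")$name  # 500 plots
  set.seed(21)
  x <- rnorm(length(un))
  for (i in seq_along(un)) {
    record_observation(st, un[i], "t1", format(x[i], digits = 10))
    record_observation(st, un[i], "t2", format(-x[i], digits = 10))
    if (i <= 2) record_observation(st, un[i], "t3", format(rnorm(1), digits = 10))
  }
  R <- correlations(st, c("t1", "t2", "t3"), units = un)
  expect_equal(diag(R), c(t1 = 1, t2 = 1, t3 = 1))
  expect_equal(R["t1", "t2"], -1)
  expect_true(is.na(R["t1", "t3"]))  # only 2 complete pairs

  # independent traits on 500 plots stay near zero
  st2 <- balanced_trial_store(genos = sprintf("H%03d", 1:100), reps = 5)
  add_trait_variable(st2, "V2", "t2", scale_class = "numeric")
  un2 <- trial_units(st2, "BAL-T1", "plot")$name
  set.seed(22)
  st2$observations <- st2$observations[0, ]
  for (i in seq_along(un2)) {
    record_observation(st2, un2[i], "toy trait", format(rnorm(1), digits = 10))
    record_observation(st2, un2[i], "t2", format(rnorm(1), digits = 10))
  }
  R2 <- correlations(st2, c("toy trait", "t2"), units = un2)
  expect_lt(abs(R2["toy trait", "t2"]), 0.15)
})

test_that("adjusted means equal raw means on balanced data", {
  st <- balanced_trial_store(genos = paste0("G", 1:5), reps = 3,
                             geno_eff = c(2, -1, 0, 4, -5),
                             block_eff = c(1, 0, -1), noise_sd = 0.3, seed = 8)
  res <- adjusted_means(st, "BAL-T1", "toy trait")
  ph <- sapply(split(
    as.numeric(st$observations$value),
    st$accessions$name[match(st$units$accession_id[match(st$observations$unit_id,
                                                         st$units$id)],
                             st$accessions$id)]), mean)
  expect_equal(res$values, ph[names(res$values)], tolerance = 1e-9)
})

test_that("adjusted means with a missing cell solve the additive normal equations", {
  st <- balanced_trial_store(genos = paste0("G", 1:4), reps = 3,
                             geno_eff = c(3, 0, -2, 1), block_eff = c(0.5, 0, -0.5),
                             noise_sd = 0.4, seed = 12)
  # drop one cell
  st$observations <- st$observations[-5, ]
  res <- adjusted_means(st, "BAL-T1", "toy trait")

  # independent oracle: explicit sum-to-zero design matrix, solved by QR
  u <- trial_units(st, "BAL-T1", "plot")
  ob <- st$observations
  acc <- st$accessions$name[match(u$accession_id[match(ob$unit_id, u$id)],
                                  st$accessions$id)]
  blk <- u$rep_number[match(ob$unit_id, u$id)]
  y <- as.numeric(ob$value)
  gl <- sort(unique(acc)); bl <- sort(unique(blk))
  Xd <- matrix(0, length(y), 1 + (length(gl) - 1) + (length(bl) - 1))
  Xd[, 1] <- 1
  for (i in seq_along(y)) {
    gi <- match(acc[i], gl); bi <- match(blk[i], bl)
    if (gi < length(gl)) Xd[i, 1 + gi] <- 1 else Xd[i, 2:length(gl)] <- -1
    off <- 1 + length(gl) - 1
    if (bi < length(bl)) Xd[i, off + bi] <- 1 else Xd[i, (off + 1):ncol(Xd)] <- -1
  }
  beta <- qr.solve(Xd, y)
  geff <- c(beta[2:length(gl)], -sum(beta[2:length(gl)]))
  oracle <- beta[1] + geff
  names(oracle) <- gl
  expect_equal(res$values, oracle[names(res$values)], tolerance = 1e-8)

  # accessions with zero observations are omitted and reported
  st2 <- balanced_trial_store(genos = paste0("G", 1:4), reps = 2)
  drop_acc <- find_accession(st2, "G4")$id
  uid <- st2$units$id[st2$units$accession_id == drop_acc]
  st2$observations <- st2$observations[!st2$observations$unit_id %in% uid, ]
  res2 <- adjusted_means(st2, "BAL-T1", "toy trait")
  expect_false("G4" %in% names(res2$values))
  expect_equal(attr(res2, "omitted"), "G4")
})

test_that("heritability follows the ANOVA variance-component formulas", {
  # construct data with exactly known mean squares: 2 genotypes x 2 reps
  # values chosen so MS_G and MS_E are hand-computable
  st <- balanced_trial_store(genos = c("Ga", "Gb"), reps = 2)
  un <- trial_units(st, "BAL-T1", "plot")
  st$observations <- st$observations[0, ]
  acc <- st$accessions$name[match(un$accession_id, st$accessions$id)]
  occ <- stats::ave(seq_along(acc), acc, FUN = seq_along)
  vals <- ifelse(acc == "Ga", c(4, 6)[occ], c(9, 11)[occ])  # within-geno var 2
  for (i in seq_len(nrow(un)))
    record_observation(st, un$name[i], "toy trait", as.character(vals[i]))
  # one-way ANOVA oracle from sums of squares
  y <- vals; g <- acc
  ms_e <- sum(tapply(y, g, function(x) sum((x - mean(x))^2))) / 2
  ms_g <- sum(tapply(y, g, function(x) 2 * (mean(x) - mean(y))^2)) / 1
  h <- heritability(st, "BAL-T1", "toy trait")
  s2g_exp <- (ms_g - ms_e) / 2
  expect_equal(h$sigma2_g, s2g_exp, tolerance = 1e-10)
  expect_equal(h$sigma2_e, ms_e, tolerance = 1e-10)
  expect_equal(h$H2, s2g_exp / (s2g_exp + ms_e), tolerance = 1e-10)

  # a dataset crafted to give MS_G = 10, MS_E = 2 at r = 2: group means
  # grand +- sqrt(2.5) (MS_G = 2 * 2 * 2.5 / 1), within-group var 2
  st2 <- balanced_trial_store(genos = c("Ga", "Gb"), reps = 2)
  un2 <- trial_units(st2, "BAL-T1", "plot")
  st2$observations <- st2$observations[0, ]
  acc2 <- st2$accessions$name[match(un2$accession_id, st2$accessions$id)]
  occ2 <- stats::ave(seq_along(acc2), acc2, FUN = seq_along)
  d <- sqrt(2.5)
  vals2 <- ifelse(acc2 == "Ga", 10 - d, 10 + d) + ifelse(occ2 == 1, -1, 1)
  for (i in seq_len(nrow(un2)))
    record_observation(st2, un2$name[i], "toy trait", format(vals2[i], digits = 12))
  h2 <- heritability(st2, "BAL-T1", "toy trait")
  expect_equal(h2$sigma2_g, 4, tolerance = 1e-9)
  expect_equal(h2$sigma2_e, 2, tolerance = 1e-9)
  expect_equal(h2$H2, 2 / 3, tolerance = 1e-9)

  # the arithmetic of the formula: MS_G 10, MS_E 2, r 2 -> 4, 2, 2/3
  # realized here through a crafted trial is overkill; verify the published
  # identity on the recovered components instead
  expect_equal(h$r, 2)

  # zero residual variance: H2 = 1
  st3 <- balanced_trial_store(genos = paste0("G", 1:5), reps = 3,
                              geno_eff = c(1, 2, 3, 4, 5), noise_sd = 0)
  expect_equal(suppressWarnings(heritability(st3, "BAL-T1", "toy trait"))$H2, 1)
  # entry-mean basis is >= plot basis
  st4 <- balanced_trial_store(genos = paste0("G", 1:10), reps = 3,
                              geno_eff = rnorm(10), noise_sd = 1, seed = 3)
  expect_gte(heritability(st4, "BAL-T1", "toy trait", basis = "entry_mean")$H2,
             heritability(st4, "BAL-T1", "toy trait")$H2)

})

test_that("pure-noise trials yield near-zero heritability", {
  set.seed(40)
  ests <- vapply(1:8, function(s) {
    st <- balanced_trial_store(genos = sprintf("G%02d", 1:30), reps = 3,
                               noise_sd = 1, seed = 100 + s)
    heritability(st, "BAL-T1", "toy trait")$H2
  }, numeric(1))
  expect_lt(mean(ests), 0.1)
})

# per-accession phenotype means, computed here independently of the package
trial_pheno_means <- function(st, trial, variable) {
  u <- trial_units(st, trial, "plot")
  ob <- st$observations[st$observations$unit_id %in% u$id, ]
  vid <- st$traits$variable_id[st$traits$variable_name == variable]
  ob <- ob[ob$variable_id == vid, ]
  acc <- st$accessions$name[match(u$accession_id[match(ob$unit_id, u$id)],
                                  st$accessions$id)]
  out <- tapply(as.numeric(ob$value), acc, mean)
  stats::setNames(as.numeric(out), names(out))
}

test_that("GBLUP limits behave: total shrinkage, no shrinkage, shift invariance", {
  sim <- simulate_program(n_founders = 30, n_crosses = 2, progeny_per_cross = 2,
                          n_markers = 120, reps = 2, seed = 17)
  st <- sim$store
  # h2 -> 0: everything shrinks to zero
  g0 <- gblup_gebv(st, "SIM-GBS", trial = "SIM-T1", variable = "yield", h2 = 0.001)
  expect_lt(max(abs(g0$values)), 0.05)
  # h2 -> 1: phenotyped accessions recover centered phenotypes
  ph <- trial_pheno_means(st, "SIM-T1", "yield")
  g1 <- gblup_gebv(st, "SIM-GBS", y = ph, h2 = 0.999)
  obs <- names(ph)
  got <- g1$values[obs] - mean(g1$values[obs])
  expect_equal(unname(got), unname(ph - mean(ph)), tolerance = 0.05)
  # adding a constant to all phenotypes leaves GEBVs unchanged
  g2 <- gblup_gebv(st, "SIM-GBS", y = ph + 100, h2 = 0.5)
  g3 <- gblup_gebv(st, "SIM-GBS", y = ph, h2 = 0.5)
  expect_equal(g2$values, g3$values, tolerance = 1e-8)
  # unphenotyped genotyped individuals receive predictions
  some <- ph[1:20]
  g4 <- gblup_gebv(st, "SIM-GBS", y = some, h2 = 0.5)
  expect_setequal(names(g4$values), names(st$genotypes[["SIM-GBS"]]))
  expect_error(gblup_gebv(st, "SIM-GBS", y = ph[1:5], h2 = 0.5),
               class = "bb_too_few")
})

test_that("selection index standardizes, weights, ranks, and round-trips", {
  st <- create_store()
  v1 <- c(A = 10, B = 20, C = 30)
  v2 <- c(A = 3, B = 2, C = 1)
  # single trait: ranking equals the trait ranking
  r1 <- selection_index(st, c(t1 = 1), values = list(t1 = v1))
  expect_equal(attr(r1, "ranking")$accession, c("C", "B", "A"))
  # weights (1, -1) with best-in-1 worst-in-2 -> top rank
  r2 <- selection_index(st, c(t1 = 1, t2 = -1), values = list(t1 = v1, t2 = v2))
  expect_equal(attr(r2, "ranking")$accession[1], "C")
  # doubling weights or rescaling an input changes nothing
  r3 <- selection_index(st, c(t1 = 2, t2 = -2), values = list(t1 = v1, t2 = v2))
  expect_equal(attr(r3, "ranking")$accession, attr(r2, "ranking")$accession)
  r4 <- selection_index(st, c(t1 = 1, t2 = -1),
                        values = list(t1 = v1 * 7 + 3, t2 = v2))
  expect_equal(r4$values, r2$values, tolerance = 1e-12)
  # missing input values exclude the accession, with a report
  r5 <- selection_index(st, c(t1 = 1, t2 = 1),
                        values = list(t1 = v1, t2 = v2[c("A", "B")]))
  expect_equal(attr(r5, "excluded"), "C")

  # stored adjusted means feed the index like primary data
  st2 <- balanced_trial_store(genos = paste0("G", 1:5), reps = 2,
                              geno_eff = c(5, 4, 3, 2, 1), noise_sd = 0)
  adjusted_means(st2, "BAL-T1", "toy trait", save_as = "means1")
  expect_s3_class(get_result(st2, "means1"), "bb_result")
  idx <- selection_index(st2, c(means1 = 1), save_as = "idx1")
  expect_equal(attr(idx, "ranking")$accession, paste0("G", 1:5))
  expect_s3_class(get_result(st2, "idx1"), "bb_result")
})

test_that("analysis results survive store persistence", {
  st <- balanced_trial_store(genos = paste0("G", 1:5), reps = 2,
                             geno_eff = c(5, 4, 3, 2, 1), noise_sd = 0)
  adjusted_means(st, "BAL-T1", "toy trait", save_as = "means1")
  f <- tempfile(fileext = ".json")
  save_store(st, f)
  st2 <- load_store(f)
  expect_equal(get_result(st2, "means1")$values, get_result(st, "means1")$values)
  idx <- selection_index(st2, c(means1 = 1))
  expect_equal(attr(idx, "ranking")$accession, paste0("G", 1:5))
})
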