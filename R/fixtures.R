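# Deterministic synthetic breeding-program generator with known ground
# truth: founder genotypes under Hardy-Weinberg equilibrium, marker
# effects, pedigree-derived progeny genotypes (independent Mendelian
# transmission per marker), alpha-design trials and phenotypes with
# configured plot-basis heritability.

#' Simulate a complete breeding program into a fresh store
#'
#' Builds a store containing founder accessions with biallelic genotypes
#' (ALT frequencies drawn Uniform(0.05, 0.95), dosages Binomial(2, p)),
#' biparental crosses with progeny whose gametes are sampled from parental
#' dosages marker-by-marker, one or more alpha-design trials, and
#' phenotypes generated as `value = mu + g + block + e` where the true
#' breeding value `g = (X - 2p) u` with marker effects
#' `u_j ~ N(0, sigma2_g / sum_j 2 p_j q_j)` (so the expected realized
#' genetic variance equals `sigma2_g`). Block effects have variance
#' `0.25 sigma2_e` and residuals variance `0.75 sigma2_e`, with
#' `sigma2_e = sigma2_g (1 - h2)/h2`, so the total non-genetic plot
#' variance matches the configured plot-basis h2. All randomness flows
#' from one seed; the same seed reproduces a byte-identical store export.
#'
#' @param n_founders founder accessions (>= 1)
#' @param n_crosses biparental crosses among founders (>= 1)
#' @param progeny_per_cross progeny saved per cross (>= 1)
#' @param n_markers biallelic SNP markers (>= 1)
#' @param n_trials alpha-design trials (>= 1)
#' @param reps replicates per trial (>= 2)
#' @param traits list of `list(name =, h2 =)` with h2 in [0, 1)
#' @param sigma2_g target additive-genetic variance
#' @param mu trait grand mean
#' @param block_size alpha incomplete-block size
#' @param seed integer seed
#' @return list with `store` (a populated `bb_store`) and `truth` (list
#'   `true_breeding_values`, `sigma2_g`, `sigma2_e` per trait,
#'   `allele_freqs`, `marker_effects`, `seed`)
#' @export
simulate_program <- function(n_founders = 50L, n_crosses = 10L,
                             progeny_per_cross = 5L, n_markers = 500L,
                             n_trials = 1L, reps = 2L,
                             traits = list(list(name = "yield", h2 = 0.5)),
                             sigma2_g = 1, mu = 100, block_size = 5L,
                             seed = 1L) {
  for (v in c(n_founders, n_crosses, progeny_per_cross, n_markers, n_trials, reps))
    if (is.na(v) || v < 1) bb_stop("bad_argument", "all counts must be >= 1")
  if (reps < 2) bb_stop("bad_argument", "reps must be >= 2 for replicated trials")
  for (tr in traits)
    if (is.null(tr$h2) || tr$h2 < 0 || tr$h2 >= 1)
      bb_stop("bad_argument", "trait h2 must be in [0, 1)")
  if (n_founders < 2 && n_crosses >= 1)
    bb_stop("bad_argument", "need >= 2 founders to cross")

  with_seed(seed, {
    store <- create_store()
    add_breeding_program(store, "SIM", "simulated breeding program")
    add_location(store, "SimStation", "Simlandia")
    ts0 <- "2020-01-01T00:00:00Z"

    founders <- sprintf("SIM-F%03d", seq_len(n_founders))
    add_accessions(store, data.frame(name = founders,
                                     species = "Manihot esculenta",
                                     stringsAsFactors = FALSE))
    p <- stats::runif(n_markers, 0.05, 0.95)
    marker_names <- sprintf("M%05d", seq_len(n_markers))
    X <- matrix(stats::rbinom(n_founders * n_markers, 2L, rep(p, each = n_founders)),
                nrow = n_founders, dimnames = list(founders, marker_names))
    u <- stats::rnorm(n_markers, 0, sqrt(sigma2_g / sum(2 * p * (1 - p))))

    create_crossing_experiment(store, "SIM-CX", "SIM", "SimStation", 2020,
                               "simulated crosses")
    prog_rows <- list()
    for (ci in seq_len(n_crosses)) {
      par <- sample(founders, 2)
      cid <- sprintf("SIM-CR%03d", ci)
      create_cross(store, "SIM-CX", cid, "biparental", par[1], par[2])
      kids <- create_progeny(store, cid, count = progeny_per_cross)
      for (kid in kids) {
        gam_f <- stats::rbinom(n_markers, 1L, X[par[1], ] / 2)
        gam_m <- stats::rbinom(n_markers, 1L, X[par[2], ] / 2)
        prog_rows[[kid]] <- gam_f + gam_m
      }
    }
    if (length(prog_rows)) {
      Xp <- do.call(rbind, prog_rows)
      dimnames(Xp) <- list(names(prog_rows), marker_names)
      X <- rbind(X, Xp)
    }
    g_true <- as.numeric(sweep(X, 2, 2 * p) %*% u)
    names(g_true) <- rownames(X)

    add_genotypes(store, "SIM-GBS",
                  scores = X,
                  markers = data.frame(name = marker_names, chrom = "1",
                                       pos = seq_len(n_markers),
                                       ref_allele = "A", alt_allele = "T",
                                       stringsAsFactors = FALSE),
                  reference_genome = "SimRef_v1", project = "SIM")

    for (ti in seq_along(traits)) {
      add_trait_variable(store,
        variable_id = sprintf("CO_999:%07d", ti),
        variable_name = traits[[ti]]$name,
        trait_name = traits[[ti]]$name, method_name = "simulated measurement",
        scale_name = "unit", scale_class = "numeric")
    }

    accs <- rownames(X)
    k <- as.integer(block_size)
    v <- (length(accs) %/% k) * k
    sigma2_e <- vapply(traits, function(tr)
      if (tr$h2 > 0) sigma2_g * (1 - tr$h2) / tr$h2 else sigma2_g, numeric(1))
    names(sigma2_e) <- vapply(traits, `[[`, character(1), "name")

    for (t in seq_len(n_trials)) {
      entries <- sort(sample(accs, v))
      lay <- generate_design("alpha", entries, block_size = k, n_reps = reps,
                             seed = sample.int(.Machine$integer.max, 1))
      lay <- assign_coordinates(lay, n_cols = max(1L, min(nrow(lay), 10L)))
      tname <- sprintf("SIM-T%d", t)
      create_trial(store, tname, "SIM", "SimStation", 2020L + t - 1L, lay,
                   trial_type = "simulated_yield_trial")
      un <- trial_units(store, tname, kind = "plot")
      acc_of <- store$accessions$name[match(un$accession_id, store$accessions$id)]
      blk_key <- paste(un$rep_number, un$block_number)
      for (ti in seq_along(traits)) {
        tr <- traits[[ti]]
        s2e <- sigma2_e[[tr$name]]
        beff <- stats::rnorm(length(unique(blk_key)), 0, sqrt(0.25 * s2e))
        names(beff) <- unique(blk_key)
        resid <- stats::rnorm(nrow(un), 0, sqrt(0.75 * s2e))
        gval <- if (tr$h2 > 0) g_true[acc_of] else 0
        yv <- mu + gval + beff[blk_key] + resid
        for (i in seq_len(nrow(un)))
          record_observation(store, un$name[i], tr$name,
                             format(yv[i], digits = 12),
                             collector = "admin", timestamp = ts0)
      }
    }

    truth <- list(true_breeding_values = g_true, sigma2_g = sigma2_g,
                  sigma2_e = as.list(sigma2_e), allele_freqs = p,
                  marker_effects = u, seed = seed)
    list(store = store, truth = truth)
  })
}
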