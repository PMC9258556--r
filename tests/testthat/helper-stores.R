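# Fixture store builders (all built in code at test time).

# Minimal registry with two programs, two locations, a handful of
# accessions and the TX303 synonym pair.
demo_store <- function() {
  st <- create_store()
  add_breeding_program(st, "IITA", "International Institute of Tropical Agriculture")
  add_breeding_program(st, "NRCRI", "National Root Crops Research Institute")
  add_location(st, "Mokwa", "Nigeria")
  add_location(st, "Ubiaja", "Nigeria")
  add_accessions(st, data.frame(
    name = c("TX303", "TMS30572", "TMEB419", "IITA-TMS-IBA000070"),
    species = c("Zea mays", rep("Manihot esculenta", 3)),
    stringsAsFactors = FALSE))
  add_synonym(st, "TX303", "Tx 303")
  st
}

# A store with trials spread over programs/years/locations and one trait,
# sized for wizard brute-force checks (~500 plots at the defaults).
wizard_store <- function(n_acc = 25, seed = 42) {
  st <- create_store()
  add_breeding_program(st, "IITA")
  add_breeding_program(st, "NRCRI")
  add_location(st, "Mokwa", "Nigeria")
  add_location(st, "Ubiaja", "Nigeria")
  accs <- sprintf("ACC%03d", seq_len(n_acc))
  add_accessions(st, data.frame(name = accs, species = "Manihot esculenta"))
  add_trait_variable(st, "CO_334:0000092", "fresh root yield",
                     scale_class = "numeric", minimum = 0)
  add_trait_variable(st, "CO_334:0000009", "plant height",
                     scale_class = "numeric", minimum = 0)
  grid <- expand.grid(prog = c("IITA", "NRCRI"), year = 2016:2018,
                      loc = c("Mokwa", "Ubiaja"), stringsAsFactors = FALSE)
  # IITA only in 2017/2018 to mirror the worked wizard example
  grid <- grid[!(grid$prog == "IITA" & grid$year == 2016), ]
  set.seed(seed)
  for (i in seq_len(nrow(grid))) {
    tn <- sprintf("%s-%s-%d-T%d", grid$prog[i], grid$loc[i], grid$year[i], i)
    lay <- generate_design("alpha", accs[1:20], block_size = 5, n_reps = 2,
                           seed = i)
    lay <- assign_coordinates(lay, 8)
    create_trial(st, tn, grid$prog[i], grid$loc[i], grid$year[i], lay,
                 trial_type = if (i %% 2 == 0) "Advanced Yield Trial" else "Preliminary Yield Trial")
    un <- trial_units(st, tn, "plot")
    # phenotype only a subset of plots so the traits dimension is selective
    for (j in seq_len(nrow(un))) {
      if (j %% 2 == 0)
        record_observation(st, un$name[j], "fresh root yield",
                           format(round(runif(1, 5, 50), 2)),
                           timestamp = "2020-01-01T00:00:00Z")
    }
  }
  st
}

# Brute-force wizard oracle: full row scan applying every predicate.
wizard_oracle <- function(st, selection) {
  u <- st$units[st$units$kind == "plot", ]
  tr <- st$trials[match(u$trial_id, st$trials$id), ]
  acc <- st$accessions$name[match(u$accession_id, st$accessions$id)]
  keep <- rep(TRUE, nrow(u))
  for (dim in names(selection)) {
    els <- selection[[dim]]
    keep <- keep & switch(dim,
      breeding_programs = tr$breeding_program %in% els,
      years = as.character(tr$year) %in% els,
      locations = tr$location %in% els,
      trials = tr$name %in% els,
      trial_types = tr$trial_type %in% els,
      accessions = acc %in% els,
      plots = u$name %in% els,
      traits = {
        vids <- st$traits$variable_id[st$traits$variable_name %in% els]
        u$id %in% st$observations$unit_id[st$observations$variable_id %in% vids]
      })
  }
  list(plots = sort(unique(u$name[keep])),
       accessions = sort(unique(acc[keep])),
       trials = sort(unique(tr$name[keep])))
}

# Registry + one balanced RCB-style trial with fully controlled values:
# value[i, j] = mu + geno_effect[i] + block_effect[j] (+ optional noise).
balanced_trial_store <- function(genos = paste0("G", 1:4), reps = 3,
                                 mu = 10, geno_eff = NULL, block_eff = NULL,
                                 noise_sd = 0, seed = 1, trial = "BAL-T1") {
  st <- create_store()
  add_breeding_program(st, "PROG")
  add_location(st, "Farm")
  add_accessions(st, data.frame(name = genos, species = "Zea mays"))
  add_trait_variable(st, "CO_000:0000001", "toy trait", scale_class = "numeric")
  v <- length(genos)
  geno_eff <- geno_eff %||% rep(0, v)
  block_eff <- block_eff %||% rep(0, reps)
  set.seed(seed)
  lay <- new_test_layout(genos, reps)
  create_trial(st, trial, "PROG", "Farm", 2021, lay)
  un <- trial_units(st, trial, "plot")
  for (i in seq_len(nrow(un))) {
    gi <- match(st$accessions$name[match(un$accession_id[i], st$accessions$id)], genos)
    bi <- un$rep_number[i]
    val <- mu + geno_eff[gi] + block_eff[bi] + rnorm(1, 0, noise_sd)
    record_observation(st, un$name[i], "toy trait", format(val, digits = 12),
                       timestamp = "2020-01-01T00:00:00Z")
  }
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A complete-block layout: rep r contains every genotype once (block = rep).
new_test_layout <- function(genos, reps) {
  v <- length(genos)
  df <- data.frame(
    plot_number = seq_len(v * reps),
    accession = as.vector(vapply(seq_len(reps), function(r) sample(genos), character(v))),
    block_number = rep(seq_len(reps), each = v),
    rep_number = rep(seq_len(reps), each = v),
    is_check = FALSE, treatment = NA_character_,
    row = NA_integer_, col = NA_integer_, stringsAsFactors = FALSE)
  attr(df, "design_type") <- "rcbd_upload"
  df
}

# Write a small VCF text fixture; gt is a markers x samples character matrix.
write_test_vcf <- function(path, samples, chrom, pos, id, ref, alt, gt) {
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_along(pos), function(i)
    paste(c(chrom[i], pos[i], id[i], ref[i], alt[i], ".", "PASS", ".", "GT",
            gt[i, ]), collapse = "\t"), character(1))
  writeLines(c(header, body), path)
  path
}
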