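# Dataset-driven analyses: trait summaries, robust outlier flagging, range
# filtering, correlations, adjusted means, broad-sense heritability, GBLUP
# breeding values and selection indices. Results are first-class objects
# that can be stored and fed back into downstream analyses.

# Resolve the observation units an analysis runs on: an explicit unit-name
# vector, a saved dataset, or a whole trial.
resolve_units <- function(store, dataset = NULL, trial = NULL, units = NULL) {
  if (!is.null(units)) return(units)
  if (!is.null(dataset)) return(resolve_dataset(store, dataset)$plots)
  if (!is.null(trial)) return(trial_units(store, trial, kind = "plot")$name)
  bb_stop("bad_argument", "supply one of dataset, trial or units")
}

# Observation values (numeric) for a variable on a set of units.
unit_values <- function(store, variable, unit_names) {
  v <- find_variable(store, variable)
  ids <- store$units$id[match(unit_names, store$units$name)]
  if (any(is.na(ids))) bb_stop("unknown_unit", "unknown observation unit in selection")
  ob <- store$observations[store$observations$variable_id == v$variable_id &
                           store$observations$unit_id %in% ids, ]
  val <- suppressWarnings(as.numeric(ob$value[match(ids, ob$unit_id)]))
  stats::setNames(val, unit_names)
}

#' Summary statistics for a trait over a dataset
#'
#' @param store a store
#' @param variable trait variable name or id
#' @param dataset saved dataset name
#' @param trial trial name (alternative to `dataset`)
#' @param units explicit observation-unit names (alternative to both)
#' @return list `n`, `mean`, `sd` (sample, n-1; `NA` when n = 1), `min`,
#'   `max`, `n_missing` (units in the selection without a valid value)
#' @export
trait_summary <- function(store, variable, dataset = NULL, trial = NULL,
                          units = NULL) {
  un <- resolve_units(store, dataset, trial, units)
  x <- unit_values(store, variable, un)
  obs <- x[!is.na(x)]
  if (length(obs) == 0) bb_stop("empty_dataset", "no observations of '%s'", variable)
  list(n = length(obs), mean = mean(obs),
       sd = if (length(obs) > 1) stats::sd(obs) else NA_real_,
       min = min(obs), max = max(obs), n_missing = sum(is.na(x)))
}

#' Flag outlying observations with a robust z-score
#'
#' Robust z = |x - median| / (1.4826 * MAD); observations with z above
#' `threshold` are flagged for review (data are never mutated). When the
#' MAD is zero the ordinary sd-based z-score is used; when both spreads are
#' zero nothing is flagged.
#'
#' @inheritParams trait_summary
#' @param threshold flag when robust z exceeds this (default 3.5)
#' @return data.frame `unit`, `value`, `z` of flagged observations
#' @export
flag_outliers <- function(store, variable, dataset = NULL, trial = NULL,
                          units = NULL, threshold = 3.5) {
  un <- resolve_units(store, dataset, trial, units)
  x <- unit_values(store, variable, un)
  x <- x[!is.na(x)]
  if (length(x) < 4) bb_stop("too_few", "outlier flagging needs >= 4 observations")
  dev <- abs(x - stats::median(x))
  scale <- stats::mad(x)  # 1.4826 * median absolute deviation
  if (scale == 0) scale <- stats::sd(x)
  if (scale == 0) return(empty_df(unit = "character", value = "numeric", z = "numeric"))
  z <- dev / scale
  flag <- z > threshold
  data.frame(unit = names(x)[flag], value = unname(x[flag]), z = unname(z[flag]),
             stringsAsFactors = FALSE)
}

#' Filter a dataset by a trait value range
#'
#' Keeps the units whose value lies in `[min, max]`; the result is a
#' character vector of unit names usable as the `units` argument of any
#' analysis, so filters compose (chaining two filters equals intersecting
#' them).
#'
#' @inheritParams trait_summary
#' @param min,max bounds (at least one required)
#' @return character vector of retained unit names
#' @export
filter_by_range <- function(store, variable, dataset = NULL, trial = NULL,
                            units = NULL, min = NULL, max = NULL) {
  if (is.null(min) && is.null(max)) bb_stop("bad_argument", "need min and/or max")
  if (!is.null(min) && !is.null(max) && min > max)
    bb_stop("bad_argument", "min > max")
  un <- resolve_units(store, dataset, trial, units)
  x <- unit_values(store, variable, un)
  keep <- !is.na(x)
  if (!is.null(min)) keep <- keep & x >= min
  if (!is.null(max)) keep <- keep & x <= max
  un[keep]
}

#' Pairwise-complete Pearson correlations among traits
#'
#' Unit-level correlation matrix; a cell with fewer than 3 complete pairs
#' is reported missing; the diagonal is 1.
#'
#' @inheritParams trait_summary
#' @param variables character vector of >= 2 variable names/ids
#' @return symmetric correlation matrix
#' @export
correlations <- function(store, variables, dataset = NULL, trial = NULL,
                         units = NULL) {
  if (length(variables) < 2) bb_stop("bad_argument", "need >= 2 variables")
  un <- resolve_units(store, dataset, trial, units)
  M <- sapply(variables, function(v) unit_values(store, v, un))
  vn <- vapply(variables, function(v) find_variable(store, v)$variable_name, character(1))
  colnames(M) <- vn
  R <- suppressWarnings(stats::cor(M, use = "pairwise.complete.obs"))
  npairs <- crossprod(!is.na(M))
  R[npairs < 3] <- NA_real_
  diag(R) <- 1
  R
}

# --------------------------------------------------------------------------
# Analysis results as first-class, storable objects.

new_result <- function(name, kind, inputs, values) {
  structure(list(name = name, kind = kind, inputs = inputs,
                 values = values, created_at = iso_time()),
            class = "bb_result")
}

#' @export
print.bb_result <- function(x, ...) {
  cat(sprintf("<breedbox analysis result '%s' (%s), %d values>\n",
              x$name, x$kind, length(x$values)))
  utils::str(utils::head(x$values))
  invisible(x)
}

#' Persist an analysis result in the store
#' @param store a store
#' @param result a `bb_result`
#' @export
save_result <- function(store, result) {
  check_store(store)
  if (!inherits(result, "bb_result")) bb_stop("bad_argument", "not a bb_result")
  if (result$name %in% names(store$results))
    bb_stop("duplicate_name", "analysis result '%s' already stored", result$name)
  store$results[[result$name]] <- result
  invisible(result$name)
}

#' Fetch a stored analysis result
#' @param store a store
#' @param name result name
#' @export
get_result <- function(store, name) {
  r <- store$results[[name]]
  if (is.null(r)) bb_stop("unknown_result", "no analysis result '%s'", name)
  r
}

# Per-accession trait values for a trial: complete-case plot observations
# tagged with accession and design structure.
trial_pheno <- function(store, trial, variable) {
  t <- find_trial(store, trial)
  u <- trial_units(store, trial, kind = "plot")
  x <- unit_values(store, variable, u$name)
  acc <- store$accessions$name[match(u$accession_id, store$accessions$id)]
  keep <- !is.na(x)
  data.frame(unit = u$name[keep], accession = acc[keep],
             rep = u$rep_number[keep], block = u$block_number[keep],
             value = unname(x[keep]), stringsAsFactors = FALSE)
}

#' Adjusted means from a two-way additive fixed-effects model
#'
#' Fits value = mu + genotype_i + block_j + error by least squares with
#' sum-to-zero constraints; the adjusted mean of genotype i is
#' `mu_hat + g_hat_i`. On balanced complete data this equals the
#' genotype's arithmetic mean; with missing cells it solves the additive
#' normal equations. Blocking uses the replicate for resolvable designs
#' (each replicate is a complete block); accessions without observations
#' are omitted and reported.
#'
#' @param store a store
#' @param trial trial name
#' @param variable trait variable
#' @param save_as optional name to persist the result under
#' @return a `bb_result` of kind `adjusted_means` with one value per
#'   accession; attribute `omitted` lists accessions without data
#' @export
adjusted_means <- function(store, trial, variable, save_as = NULL) {
  ph <- trial_pheno(store, trial, variable)
  if (nrow(ph) == 0) bb_stop("empty_dataset", "no observations of '%s' in '%s'",
                             variable, trial)
  if (length(unique(ph$rep)) < 2)
    bb_stop("too_few", "adjusted means need >= 2 replicates/blocks")
  all_acc <- unique(store$accessions$name[match(
    trial_units(store, trial, "plot")$accession_id, store$accessions$id)])
  omitted <- setdiff(all_acc, ph$accession)
  g <- factor(ph$accession)
  b <- factor(ph$rep)
  if (nlevels(g) < 2) bb_stop("too_few", "need >= 2 genotypes")
  fit <- stats::lm(value ~ g + b, data = data.frame(value = ph$value, g = g, b = b),
                   contrasts = list(g = "contr.sum", b = "contr.sum"))
  cf <- stats::coef(fit)
  mu <- cf[["(Intercept)"]]
  ng <- nlevels(g)
  geff <- cf[grep("^g[0-9]+$", names(cf))]
  geff <- c(geff, -sum(geff))  # sum-to-zero: last level is minus the rest
  names(geff) <- levels(g)
  vals <- sort_named(mu + geff)
  res <- new_result(save_as %||% sprintf("%s:%s:adjusted_means", trial, variable),
                    "adjusted_means",
                    list(trial = trial, variable = variable), vals)
  attr(res, "omitted") <- omitted
  if (!is.null(save_as)) save_result(store, res)
  res
}

sort_named <- function(x) x[order(names(x))]

#' Broad-sense heritability from one-way ANOVA
#'
#' Complete-case random-effects ANOVA by genotype:
#' `sigma2_g = (MS_G - MS_E) / r` (truncated at 0), `sigma2_e = MS_E`,
#' and plot-basis `H2 = sigma2_g / (sigma2_g + sigma2_e)`. The replication
#' coefficient r is the standard one-way ANOVA coefficient
#' `(N - sum n_i^2 / N) / (G - 1)`, which equals the replicate count for
#' balanced data. `basis = "entry_mean"` returns
#' `sigma2_g / (sigma2_g + sigma2_e / r)` instead.
#'
#' @param store a store
#' @param trial trial name (must have >= 2 replicates)
#' @param variable trait variable
#' @param basis `"plot"` (default) or `"entry_mean"`
#' @return list `H2`, `sigma2_g`, `sigma2_e`, `r`
#' @export
heritability <- function(store, trial, variable, basis = c("plot", "entry_mean")) {
  basis <- match.arg(basis)
  ph <- trial_pheno(store, trial, variable)
  if (nrow(ph) == 0) bb_stop("empty_dataset", "no observations")
  if (length(unique(ph$rep)) < 2) bb_stop("too_few", "heritability needs >= 2 replicates")
  g <- factor(ph$accession)
  counts <- table(g)
  keep <- ph$accession %in% names(counts)[counts >= 2]
  ph <- ph[keep, ]; g <- factor(ph$accession)
  if (nlevels(g) < 2) bb_stop("too_few", "need >= 2 replicated genotypes")
  aovtab <- stats::anova(stats::lm(ph$value ~ g))
  ms_g <- aovtab$`Mean Sq`[1]
  ms_e <- aovtab$`Mean Sq`[2]
  N <- nrow(ph); ni <- as.integer(table(g))
  r <- (N - sum(ni^2) / N) / (nlevels(g) - 1)
  comps <- heritability_from_ms(ms_g, ms_e, r, basis)
  c(comps, list(r = r))
}

# Variance components and H2 from ANOVA mean squares; shared by the
# data path above and directly testable against hand-computed tables.
heritability_from_ms <- function(ms_g, ms_e, r, basis = "plot") {
  s2g <- max(0, (ms_g - ms_e) / r)
  s2e <- ms_e
  H2 <- if (basis == "plot") s2g / (s2g + s2e) else s2g / (s2g + s2e / r)
  list(H2 = H2, sigma2_g = s2g, sigma2_e = s2e)
}

#' GBLUP breeding values from the genomic relationship matrix
#'
#' Mixed model `y = 1 mu + g + e` with `g ~ N(0, G sigma2_g)`. Given
#' heritability h2, the shrinkage parameter is `lambda = (1 - h2)/h2` and
#' `g_hat = G[, obs] (G[obs, obs] + lambda I)^{-1} (y - mu_hat)` with the
#' GLS intercept; unphenotyped but genotyped individuals get predictions
#' through the G blocks. When `h2` is omitted it is estimated by
#' maximizing the restricted likelihood over (0.01, 0.99) via
#' golden-section search on the eigendecomposition of G. Phenotypes can be
#' a named vector, a stored analysis result (e.g. adjusted means), or a
#' trial/variable pair (per-accession means).
#'
#' @param store a store
#' @param protocol genotyping protocol supplying the GRM
#' @param y named numeric vector of per-accession phenotypes
#' @param result stored analysis-result name to use as phenotypes
#' @param trial,variable trial and trait to average per accession
#' @param h2 heritability in (0, 1); estimated by REML when `NULL`
#' @param save_as optional name to persist the result under
#' @return a `bb_result` of kind `gebv` with one GEBV per genotyped
#'   individual; attributes `h2` (used) and `n_obs`
#' @export
gblup_gebv <- function(store, protocol, y = NULL, result = NULL, trial = NULL,
                       variable = NULL, h2 = NULL, save_as = NULL) {
  check_store(store)
  if (is.null(y)) {
    if (!is.null(result)) {
      y <- get_result(store, result)$values
    } else if (!is.null(trial) && !is.null(variable)) {
      ph <- trial_pheno(store, trial, variable)
      y <- tapply(ph$value, ph$accession, mean)
      y <- stats::setNames(as.numeric(y), names(y))
    } else bb_stop("bad_argument", "supply y, result, or trial+variable")
  }
  geno <- store$genotypes[[protocol]]
  if (is.null(geno)) bb_stop("unknown_protocol", "no protocol '%s'", protocol)
  all_s <- names(geno)
  obs <- intersect(names(y)[!is.na(y)], all_s)
  if (length(obs) < 10)
    bb_stop("too_few", "phenotypes and genotypes overlap on %d < 10 accessions",
            length(obs))
  G <- grm(store, protocol)
  Goo <- G[obs, obs]
  yo <- y[obs]
  if (is.null(h2)) h2 <- reml_h2(yo, Goo)
  lambda <- (1 - h2) / h2
  C <- Goo + diag(lambda, length(obs))
  sol <- tryCatch(solve(C), error = function(e) NULL)
  if (is.null(sol)) {
    C <- C + diag(1e-8, length(obs))
    sol <- tryCatch(solve(C), error = function(e)
      bb_stop("singular", "G + lambda I is singular"))
  }
  one <- rep(1, length(obs))
  Vi1 <- sol %*% one
  mu <- as.numeric(crossprod(Vi1, yo) / crossprod(one, Vi1))
  alpha <- sol %*% (yo - mu)
  gebv <- as.numeric(G[, obs, drop = FALSE] %*% alpha)
  names(gebv) <- rownames(G)
  res <- new_result(save_as %||% sprintf("gebv:%s", protocol), "gebv",
                    list(protocol = protocol, h2 = h2), sort_named(gebv))
  attr(res, "h2") <- h2
  attr(res, "n_obs") <- length(obs)
  if (!is.null(save_as)) save_result(store, res)
  res
}

# Profile REML of h2 for y = 1 mu + g + e, V propto h2 G + (1-h2) I,
# via one eigendecomposition of G. Minimised by stats::optimize
# (golden-section search) on (0.01, 0.99).
reml_h2 <- function(y, G) {
  n <- length(y)
  E <- eigen(G, symmetric = TRUE)
  d <- pmax(E$values, 0)
  yt <- as.numeric(crossprod(E$vectors, y))
  ot <- as.numeric(crossprod(E$vectors, rep(1, n)))
  negll <- function(h2) {
    k <- h2 * d + (1 - h2)
    w <- 1 / k
    oVo <- sum(ot^2 * w)
    oVy <- sum(ot * yt * w)
    yVy <- sum(yt^2 * w)
    yPy <- max(yVy - oVy^2 / oVo, 1e-12)
    s2 <- yPy / (n - 1)
    0.5 * (sum(log(k)) + log(oVo) + (n - 1) * log(s2))
  }
  stats::optimize(negll, c(0.01, 0.99))$minimum
}

#' Weighted standardized selection index
#'
#' Each input is standardized to zero mean and unit variance over the
#' accessions carrying all inputs, then combined as `index = sum_k w_k
#' z_k`; accessions are ranked by descending index (ties broken by name).
#' Inputs may be stored analysis-result names or named numeric vectors, so
#' adjusted means and GEBVs feed in like primary data.
#'
#' @param store a store
#' @param weights named numeric vector: input name -> weight. Each name
#'   must be a stored analysis result, unless supplied in `values`
#' @param values optional named list of named numeric vectors overriding /
#'   complementing stored results
#' @param save_as optional name to persist the index under
#' @return a `bb_result` of kind `selection_index`; attribute `ranking` is
#'   a data.frame (accession, index, rank), attribute `excluded` lists
#'   accessions missing any input
#' @export
selection_index <- function(store, weights, values = NULL, save_as = NULL) {
  check_store(store)
  if (length(weights) < 1 || is.null(names(weights)))
    bb_stop("bad_argument", "weights must be a named numeric vector")
  if (any(!is.finite(weights))) bb_stop("bad_argument", "weights must be finite")
  inputs <- lapply(names(weights), function(nm) {
    if (!is.null(values) && nm %in% names(values)) return(values[[nm]])
    get_result(store, nm)$values
  })
  common <- Reduce(intersect, lapply(inputs, function(v) names(v)[!is.na(v)]))
  all_acc <- unique(unlist(lapply(inputs, names)))
  excluded <- setdiff(all_acc, common)
  if (length(common) < 2) bb_stop("too_few", "fewer than 2 accessions carry every input")
  Z <- vapply(inputs, function(v) {
    x <- v[common]
    s <- stats::sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }, numeric(length(common)))
  idx <- as.numeric(Z %*% weights)
  names(idx) <- common
  ord <- order(-idx, names(idx))
  ranking <- data.frame(accession = names(idx)[ord], index = idx[ord],
                        rank = seq_along(ord), stringsAsFactors = FALSE,
                        row.names = NULL)
  res <- new_result(save_as %||% "selection_index", "selection_index",
                    list(weights = weights), sort_named(idx))
  attr(res, "ranking") <- ranking
  attr(res, "excluded") <- excluded
  if (!is.null(save_as)) save_result(store, res)
  res
}
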