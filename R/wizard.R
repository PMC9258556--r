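# Search-wizard style faceted querying: the store's plot-level data is a
# cube that can be cut along dimensions; elements within a dimension
# combine by union, dimensions combine by intersection.

WIZARD_DIMENSIONS <- c("breeding_programs", "years", "locations", "trials",
                       "accessions", "traits", "trial_types", "plots")

# One row per plot observation unit with every queryable dimension.
plot_table <- function(store) {
  u <- store$units[store$units$kind == "plot", , drop = FALSE]
  if (nrow(u) == 0) {
    return(empty_df(plots = "character", accessions = "character",
                    trials = "character", breeding_programs = "character",
                    locations = "character", years = "character",
                    trial_types = "character", unit_id = "integer"))
  }
  tr <- store$trials[match(u$trial_id, store$trials$id), ]
  data.frame(
    plots = u$name,
    accessions = store$accessions$name[match(u$accession_id, store$accessions$id)],
    trials = tr$name,
    breeding_programs = tr$breeding_program,
    locations = tr$location,
    years = as.character(tr$year),
    trial_types = tr$trial_type,
    unit_id = u$id,
    stringsAsFactors = FALSE)
}

# Variable names observed on a set of unit ids (the "traits" dimension).
unit_traits <- function(store, unit_ids) {
  ob <- store$observations[store$observations$unit_id %in% unit_ids, , drop = FALSE]
  vn <- store$traits$variable_name[match(ob$variable_id, store$traits$variable_id)]
  split(vn, factor(ob$unit_id, levels = unit_ids))
}

dimension_values <- function(store, dimension) {
  switch(dimension,
    breeding_programs = store$programs$name,
    locations = store$locations$name,
    trials = store$trials$name,
    years = sort(unique(as.character(store$trials$year))),
    trial_types = sort(unique(store$trials$trial_type)),
    accessions = store$accessions$name,
    plots = store$units$name[store$units$kind == "plot"],
    traits = store$traits$variable_name,
    bb_stop("unknown_dimension", "unknown dimension '%s'", dimension))
}

check_selection <- function(store, selection) {
  if (length(selection) == 0) return(invisible(selection))
  dims <- names(selection)
  if (is.null(dims) || any(!nzchar(dims)))
    bb_stop("bad_selection", "selection must be a named list of dimension = elements")
  bad <- setdiff(dims, WIZARD_DIMENSIONS)
  if (length(bad)) bb_stop("unknown_dimension", "unknown dimension '%s'", bad[1])
  if (anyDuplicated(dims)) bb_stop("bad_selection", "dimensions must be distinct")
  if (length(dims) > store$config$wizard_max_steps)
    bb_stop("bad_selection", "at most %d selection steps", store$config$wizard_max_steps)
  invisible(selection)
}

# Plot-table rows satisfying every step of the selection.
selected_rows <- function(store, selection) {
  pt <- plot_table(store)
  keep <- rep(TRUE, nrow(pt))
  for (dim in names(selection)) {
    els <- as.character(selection[[dim]])
    if (dim == "traits") {
      ids <- store$traits$variable_id[store$traits$variable_name %in% els]
      with_obs <- unique(store$observations$unit_id[
        store$observations$variable_id %in% ids])
      keep <- keep & pt$unit_id %in% with_obs
    } else {
      keep <- keep & pt[[dim]] %in% els
    }
  }
  pt[keep, , drop = FALSE]
}

#' Available elements for the next wizard dimension
#'
#' Given the steps selected so far, returns exactly the elements of
#' `next_dimension` attached to at least one plot satisfying the current
#' selection; with an empty selection, all elements of that dimension.
#'
#' @param store a store
#' @param selection named list `dimension = character vector of elements`
#'   (0 to 4 steps, distinct dimensions)
#' @param next_dimension dimension to list options for (must not already be
#'   in the selection)
#' @return sorted character vector
#' @export
wizard_options <- function(store, selection = list(), next_dimension) {
  check_store(store)
  check_selection(store, selection)
  if (!next_dimension %in% WIZARD_DIMENSIONS)
    bb_stop("unknown_dimension", "unknown dimension '%s'", next_dimension)
  if (next_dimension %in% names(selection))
    bb_stop("bad_selection", "dimension '%s' already selected", next_dimension)
  if (length(selection) == 0 && next_dimension != "traits")
    return(sort(unique(dimension_values(store, next_dimension))))
  rows <- selected_rows(store, selection)
  if (next_dimension == "traits") {
    ob <- store$observations[store$observations$unit_id %in% rows$unit_id, ]
    vn <- store$traits$variable_name[match(unique(ob$variable_id), store$traits$variable_id)]
    return(sort(vn))
  }
  sort(unique(rows[[next_dimension]]))
}

#' Execute a wizard selection
#'
#' Within a dimension, elements combine by union; across dimensions, by
#' intersection. The traits dimension keeps plots having at least one
#' observation of a selected trait.
#'
#' @inheritParams wizard_options
#' @return list with sorted character vectors `plots`, `accessions`,
#'   `trials`
#' @export
wizard_query <- function(store, selection = list()) {
  check_store(store)
  check_selection(store, selection)
  rows <- selected_rows(store, selection)
  list(plots = sort(unique(rows$plots)),
       accessions = sort(unique(rows$accessions)),
       trials = sort(unique(rows$trials)))
}

#' Save a wizard selection as a named dataset
#'
#' Datasets are late-bound: resolving re-executes the stored selection
#' against the current store, so data added later is included.
#'
#' @inheritParams wizard_options
#' @param name unique dataset name
#' @param owner owning account
#' @export
save_dataset <- function(store, name, selection, owner = "admin") {
  check_store(store)
  assert_scalar_chr(name, "dataset name")
  check_selection(store, selection)
  if (name %in% names(store$datasets))
    bb_stop("duplicate_name", "dataset '%s' already exists", name)
  store$datasets[[name]] <- list(name = name,
                                 selection = lapply(selection, as.character),
                                 owner = owner)
  invisible(name)
}

#' Resolve a saved dataset against the current store
#' @param store a store
#' @param name dataset name
#' @return as [wizard_query()]
#' @export
resolve_dataset <- function(store, name) {
  check_store(store)
  d <- store$datasets[[name]]
  if (is.null(d)) bb_stop("unknown_dataset", "no dataset '%s'", name)
  wizard_query(store, d$selection)
}
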