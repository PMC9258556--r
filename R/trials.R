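# Phenotyping trials: trial storage, observation units at plot / plant /
# tissue level, management factors, and collection-file round-tripping.

COLLECTION_ID_COLS <- c("observationunit_name", "accession_name", "plot_number",
                        "block_number", "rep_number", "row_number", "col_number")

#' Store a trial with its field layout
#'
#' Creates the trial record plus one plot observation unit per layout row,
#' named `<trial_name>-PLOT_<plot_number>`. Every layout accession must
#' resolve in the registry; program and location must exist; the year must
#' be plausible (1900-2100). Creating data in a program requires the
#' matching program role (or curator).
#'
#' @param store a store
#' @param name unique trial name
#' @param breeding_program existing breeding program name
#' @param location existing location name
#' @param year harvest year
#' @param layout a `bb_layout` from [generate_design()] (optionally with
#'   coordinates from [assign_coordinates()]), or a data.frame with the
#'   same columns for uploaded layouts
#' @param trial_type free-text trial type (e.g. "Advanced Yield Trial")
#' @param plot_width,plot_length plot dimensions in meters (optional)
#' @param field_size field size in hectares (optional)
#' @param user acting account
#' @return the trial id (invisibly)
#' @export
create_trial <- function(store, name, breeding_program, location, year, layout,
                         trial_type = "phenotyping_trial",
                         plot_width = NA_real_, plot_length = NA_real_,
                         field_size = NA_real_, user = "admin") {
  check_store(store)
  assert_scalar_chr(name, "trial name")
  require_auth(store, user, "create", object_program = breeding_program)
  if (name %in% store$trials$name) bb_stop("duplicate_name", "trial '%s' already exists", name)
  if (!breeding_program %in% store$programs$name)
    bb_stop("unknown_program", "no breeding program '%s'", breeding_program)
  if (!location %in% store$locations$name)
    bb_stop("unknown_location", "no location '%s'", location)
  year <- as.integer(year)
  if (is.na(year) || year < 1900 || year > 2100)
    bb_stop("bad_argument", "implausible year %s", year)
  acc_ids <- integer(nrow(layout))
  for (i in seq_len(nrow(layout))) {
    acc <- find_accession(store, layout$accession[i])
    if (is.null(acc)) bb_stop("unknown_accession", "layout accession '%s' not in registry",
                              layout$accession[i])
    acc_ids[i] <- acc$id
  }
  tid <- new_id(store)
  store$trials <- df_append(store$trials, list(
    id = tid, name = name, breeding_program = breeding_program,
    location = location, year = year, trial_type = trial_type,
    design_type = attr(layout, "design_type") %||% "uploaded",
    plot_width = plot_width, plot_length = plot_length,
    field_size = field_size, owner = user))
  ids <- store$counter + seq_len(nrow(layout))
  store$counter <- store$counter + nrow(layout)
  plot_names <- sprintf("%s-PLOT_%d", name, layout$plot_number)
  if (any(plot_names %in% store$units$name))
    bb_stop("duplicate_name", "plot names for trial '%s' already exist", name)
  trt <- if ("treatment" %in% names(layout)) as.character(layout$treatment) else NA_character_
  store$units <- rbind(store$units, data.frame(
    id = as.integer(ids), name = plot_names, kind = "plot", trial_id = tid,
    accession_id = acc_ids, plot_number = as.integer(layout$plot_number),
    block_number = as.integer(layout$block_number),
    rep_number = as.integer(layout$rep_number),
    row = as.integer(layout$row), col = as.integer(layout$col),
    is_check = layout$is_check, parent_id = NA_integer_,
    treatment = trt, stringsAsFactors = FALSE))
  invisible(tid)
}

find_trial <- function(store, name) {
  i <- match(name, store$trials$name)
  if (is.na(i)) bb_stop("unknown_trial", "no trial '%s'", name)
  as.list(store$trials[i, , drop = FALSE])
}

#' Observation units of a trial
#' @param store a store
#' @param trial trial name
#' @param kind optionally restrict to `plot`, `plant` or `tissue_sample`
#' @export
trial_units <- function(store, trial, kind = NULL) {
  t <- find_trial(store, trial)
  u <- store$units[store$units$trial_id == t$id, , drop = FALSE]
  if (!is.null(kind)) u <- u[u$kind == kind, , drop = FALSE]
  u
}

#' Create plant-level entries for every plot of a trial
#'
#' Plant units are named `<plot_name>_plant_<i>` and linked to their plot,
#' giving stable barcode-ready identifiers. Re-running is an error (no
#' silent duplication).
#'
#' @param store a store
#' @param trial trial name
#' @param plants_per_plot number of plants per plot (>= 1)
#' @return character vector of new unit names (invisibly)
#' @export
create_plant_entries <- function(store, trial, plants_per_plot) {
  check_store(store)
  if (plants_per_plot < 1) bb_stop("bad_argument", "plants_per_plot must be >= 1")
  plots <- trial_units(store, trial, kind = "plot")
  t <- find_trial(store, trial)
  existing <- store$units$kind == "plant" & store$units$trial_id == t$id
  if (any(existing)) bb_stop("already_exists", "trial '%s' already has plant entries", trial)
  nm <- character(0)
  rows <- list()
  for (i in seq_len(nrow(plots))) {
    for (j in seq_len(plants_per_plot)) {
      nm1 <- sprintf("%s_plant_%d", plots$name[i], j)
      rows[[length(rows) + 1L]] <- list(
        id = new_id(store), name = nm1, kind = "plant", trial_id = t$id,
        accession_id = plots$accession_id[i], plot_number = plots$plot_number[i],
        block_number = plots$block_number[i], rep_number = plots$rep_number[i],
        row = plots$row[i], col = plots$col[i], is_check = plots$is_check[i],
        parent_id = plots$id[i], treatment = plots$treatment[i])
      nm <- c(nm, nm1)
    }
  }
  store$units <- rbind(store$units,
                       do.call(rbind, lapply(rows, as.data.frame, stringsAsFactors = FALSE)))
  invisible(nm)
}

#' Create tissue-sample entries under given units
#'
#' Samples are named `<unit_name>_tissue_<i>`; the parent chain ends in a
#' plot (parents may be plots or plants).
#'
#' @param store a store
#' @param unit_names parent unit names (plots or plants)
#' @param count samples per parent (>= 1)
#' @return character vector of new unit names (invisibly)
#' @export
create_tissue_samples <- function(store, unit_names, count) {
  check_store(store)
  if (count < 1) bb_stop("bad_argument", "count must be >= 1")
  nm <- character(0)
  for (un in unit_names) {
    i <- match(un, store$units$name)
    if (is.na(i)) bb_stop("unknown_unit", "no observation unit '%s'", un)
    if (store$units$kind[i] == "tissue_sample")
      bb_stop("bad_argument", "cannot sample from a tissue sample")
    for (j in seq_len(count)) {
      nm1 <- sprintf("%s_tissue_%d", un, j)
      if (nm1 %in% store$units$name) bb_stop("already_exists", "unit '%s' already exists", nm1)
      store$units <- df_append(store$units, list(
        id = new_id(store), name = nm1, kind = "tissue_sample",
        trial_id = store$units$trial_id[i], accession_id = store$units$accession_id[i],
        plot_number = store$units$plot_number[i], block_number = store$units$block_number[i],
        rep_number = store$units$rep_number[i], row = store$units$row[i],
        col = store$units$col[i], is_check = store$units$is_check[i],
        parent_id = store$units$id[i], treatment = store$units$treatment[i]))
      nm <- c(nm, nm1)
    }
  }
  invisible(nm)
}

#' Record a single phenotype observation
#'
#' The value is validated against the variable's scale; an invalid value is
#' an error (bulk import reports violations instead, see
#' [import_phenotypes()]). A repeated observation of the same variable on
#' the same unit replaces the previous value.
#'
#' @param store a store
#' @param unit observation unit name
#' @param variable trait variable id or name
#' @param value value as text
#' @param collector recording account
#' @param timestamp ISO-8601 UTC timestamp (defaults to now)
#' @export
record_observation <- function(store, unit, variable, value,
                               collector = "admin", timestamp = NULL) {
  check_store(store)
  i <- match(unit, store$units$name)
  if (is.na(i)) bb_stop("unknown_unit", "no observation unit '%s'", unit)
  v <- find_variable(store, variable)
  chk <- validate_value(store, v$variable_id, value)
  if (!chk$ok) bb_stop("invalid_value", "value '%s' invalid for %s: %s",
                       value, v$variable_name, chk$reason)
  ts <- timestamp %||% iso_time()
  uid <- store$units$id[i]
  prev <- store$observations$unit_id == uid &
    store$observations$variable_id == v$variable_id
  if (any(prev)) store$observations <- store$observations[!prev, , drop = FALSE]
  store$observations <- df_append(store$observations, list(
    unit_id = uid, variable_id = v$variable_id, value = as.character(value),
    timestamp = ts, collector = collector))
  invisible(store)
}

#' Export a phenotype collection file for a trial
#'
#' Writes a Field-Book style flat CSV: the identifier columns
#' `observationunit_name,accession_name,plot_number,block_number,
#' rep_number,row_number,col_number` followed by one column per requested
#' variable, prefilled with any stored observations (empty otherwise).
#' Export, fill, [import_phenotypes()] and re-export reproduce the filled
#' file on valid cells.
#'
#' @param store a store
#' @param trial trial name
#' @param variables character vector of variable names or ids
#' @param path output CSV path
#' @param kind observation-unit level to export (default `plot`)
#' @return the path (invisibly)
#' @export
export_collection_file <- function(store, trial, variables, path, kind = "plot") {
  check_store(store)
  u <- trial_units(store, trial, kind = kind)
  vars <- lapply(variables, function(x) find_variable(store, x))
  out <- data.frame(
    observationunit_name = u$name,
    accession_name = store$accessions$name[match(u$accession_id, store$accessions$id)],
    plot_number = u$plot_number, block_number = u$block_number,
    rep_number = u$rep_number, row_number = u$row, col_number = u$col,
    stringsAsFactors = FALSE, check.names = FALSE)
  for (v in vars) {
    ob <- store$observations[store$observations$variable_id == v$variable_id, ]
    out[[v$variable_name]] <- ob$value[match(u$id, ob$unit_id)]
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Import a filled phenotype collection file
#'
#' Rows are matched to observation units by `observationunit_name`; every
#' non-empty cell is validated against its variable's scale. Valid cells
#' are stored; invalid cells, unknown rows and unrecognized trait columns
#' are reported, never silently dropped. A file with no recognized trait
#' column is an error.
#'
#' @param store a store
#' @param path collection CSV
#' @param collector account recorded on the observations
#' @param timestamp optional fixed ISO-8601 timestamp for all observations
#' @return report list: `stored` (count), `rejected_cells` (data.frame
#'   unit/variable/value/reason), `unknown_units`, `unknown_columns`
#' @export
import_phenotypes <- function(store, path, collector = "admin", timestamp = NULL) {
  check_store(store)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  if (!"observationunit_name" %in% names(df))
    bb_stop("bad_file", "collection file lacks observationunit_name column")
  other <- setdiff(names(df), COLLECTION_ID_COLS)
  known_vars <- other[other %in% store$traits$variable_name |
                      other %in% store$traits$variable_id]
  unknown_cols <- setdiff(other, known_vars)
  if (length(known_vars) == 0)
    bb_stop("bad_file", "collection file has no recognized trait columns")
  report <- list(stored = 0L,
                 rejected_cells = empty_df(unit = "character", variable = "character",
                                           value = "character", reason = "character"),
                 unknown_units = character(0), unknown_columns = unknown_cols)
  for (r in seq_len(nrow(df))) {
    un <- df$observationunit_name[r]
    if (!un %in% store$units$name) {
      report$unknown_units <- c(report$unknown_units, un)
      next
    }
    for (vc in known_vars) {
      val <- df[[vc]][r]
      if (is.na(val) || !nzchar(trimws(val))) next
      v <- find_variable(store, vc)
      chk <- validate_value(store, v$variable_id, val)
      if (chk$ok) {
        record_observation(store, un, v$variable_id, val,
                           collector = collector, timestamp = timestamp)
        report$stored <- report$stored + 1L
      } else {
        report$rejected_cells <- df_append(report$rejected_cells, list(
          unit = un, variable = v$variable_name, value = val, reason = chk$reason))
      }
    }
  }
  report
}

#' Attach a field-management factor to a trial
#'
#' Key/value agronomic metadata (e.g. fertilizer regime). Factor names are
#' unique per trial.
#'
#' @param store a store
#' @param trial trial name
#' @param name factor name
#' @param value factor value
#' @export
add_management_factor <- function(store, trial, name, value) {
  check_store(store)
  t <- find_trial(store, trial)
  if (any(store$trial_factors$trial_id == t$id & store$trial_factors$name == name))
    bb_stop("duplicate_name", "trial '%s' already has factor '%s'", trial, name)
  store$trial_factors <- df_append(store$trial_factors, list(
    trial_id = t$id, name = name, value = as.character(value)))
  invisible(store)
}

#' Management factors of a trial
#' @inheritParams add_management_factor
#' @return named character vector
#' @export
management_factors <- function(store, trial) {
  t <- find_trial(store, trial)
  f <- store$trial_factors[store$trial_factors$trial_id == t$id, ]
  stats::setNames(f$value, f$name)
}
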