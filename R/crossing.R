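# Crossing experiments, typed crosses, cross properties, families and
# progeny creation with automatic pedigrees.

CROSS_TYPES <- c("biparental", "self", "sib", "open_pollinated", "bulk",
                 "bulk_selfed", "bulk_open", "doubled_haploid", "polycross",
                 "reciprocal", "multicross")

# Parent requirements per cross type:
#   both    - male must resolve to an accession
#   selfed  - male recorded as the female itself
#   female  - male optional; when given it may be a population name and is
#             stored as text (open-pollinated style) without resolution
CROSS_MALE_RULE <- c(
  biparental = "both", reciprocal = "both", sib = "both",
  self = "selfed", doubled_haploid = "selfed", bulk_selfed = "selfed",
  open_pollinated = "female", bulk_open = "female",
  bulk = "female", polycross = "female", multicross = "female")

#' Create a crossing experiment
#'
#' The top-level container for crosses: a unique name, breeding program,
#' location, year and description.
#'
#' @param store a store
#' @param name unique experiment name
#' @param breeding_program existing program
#' @param location existing location
#' @param year year
#' @param description free text
#' @param user acting account
#' @export
create_crossing_experiment <- function(store, name, breeding_program, location,
                                       year, description = "", user = "admin") {
  check_store(store)
  assert_scalar_chr(name, "experiment name")
  require_auth(store, user, "create", object_program = breeding_program)
  if (name %in% store$crossing_experiments$name)
    bb_stop("duplicate_name", "crossing experiment '%s' already exists", name)
  if (!breeding_program %in% store$programs$name)
    bb_stop("unknown_program", "no breeding program '%s'", breeding_program)
  if (!location %in% store$locations$name)
    bb_stop("unknown_location", "no location '%s'", location)
  id <- new_id(store)
  store$crossing_experiments <- df_append(store$crossing_experiments, list(
    id = id, name = name, breeding_program = breeding_program,
    location = location, year = as.integer(year), description = description,
    owner = user))
  invisible(id)
}

#' Create a typed cross
#'
#' Parent requirements depend on the cross type: biparental, reciprocal and
#' sib crosses require both parents as accessions; self, doubled-haploid
#' and bulk-selfed crosses record the female as male too; open-pollinated
#' and bulk/bulk-open/polycross/multicross crosses require only the female
#' (an optional male may be a population name and is stored as given).
#' Plot- or plant-level parent units are optional detail.
#'
#' @param store a store
#' @param experiment crossing experiment name
#' @param cross_unique_id unique cross identifier
#' @param cross_type one of the 11 supported types (see `CROSS_TYPES`)
#' @param female female parent accession name
#' @param male male parent accession (or population name where allowed)
#' @param female_unit,male_unit optional parental plot/plant unit names
#' @param family_name optional family grouping label
#' @param user acting account
#' @return the cross id (invisibly)
#' @export
create_cross <- function(store, experiment, cross_unique_id, cross_type,
                         female, male = NULL, female_unit = NULL,
                         male_unit = NULL, family_name = NA_character_,
                         user = "admin") {
  check_store(store)
  i <- match(experiment, store$crossing_experiments$name)
  if (is.na(i)) bb_stop("unknown_experiment", "no crossing experiment '%s'", experiment)
  require_auth(store, user, "create",
               object_program = store$crossing_experiments$breeding_program[i])
  if (!cross_type %in% CROSS_TYPES)
    bb_stop("unknown_cross_type", "unknown cross type '%s'", cross_type)
  if (cross_unique_id %in% store$crosses$cross_unique_id)
    bb_stop("duplicate_name", "cross '%s' already exists", cross_unique_id)
  fem <- find_accession(store, female)
  if (is.null(fem)) bb_stop("unknown_parent", "female parent '%s' not in registry", female)
  rule <- CROSS_MALE_RULE[[cross_type]]
  male_name <- switch(rule,
    both = {
      if (is.null(male)) bb_stop("missing_male_parent",
                                 "cross type '%s' requires a male parent", cross_type)
      m <- find_accession(store, male)
      if (is.null(m)) bb_stop("unknown_parent", "male parent '%s' not in registry", male)
      m$name
    },
    selfed = fem$name,
    female = if (is.null(male)) NA_character_ else as.character(male))
  for (un in c(female_unit, male_unit))
    if (!is.null(un) && !un %in% store$units$name)
      bb_stop("unknown_unit", "parental unit '%s' not in store", un)
  id <- new_id(store)
  store$crosses <- df_append(store$crosses, list(
    id = id, cross_unique_id = cross_unique_id,
    experiment_id = store$crossing_experiments$id[i], cross_type = cross_type,
    female_parent = fem$name, male_parent = male_name,
    female_unit = female_unit %||% NA_character_,
    male_unit = male_unit %||% NA_character_,
    family_name = family_name %||% NA_character_, owner = user))
  invisible(id)
}

find_cross <- function(store, cross_unique_id) {
  i <- match(cross_unique_id, store$crosses$cross_unique_id)
  if (is.na(i)) bb_stop("unknown_cross", "no cross '%s'", cross_unique_id)
  as.list(store$crosses[i, , drop = FALSE])
}

#' Annotate a cross with evaluation properties
#'
#' Allowed keys come from the instance configuration (default: pollination
#' date, tag number, number of flowers, number of bags, number of fruits,
#' number of seeds). Count-valued properties must be non-negative integers
#' and the pollination date must be ISO-8601.
#'
#' @param store a store
#' @param cross_unique_id cross identifier
#' @param properties named list/vector of property values
#' @export
set_cross_properties <- function(store, cross_unique_id, properties) {
  check_store(store)
  find_cross(store, cross_unique_id)
  allowed <- store$config$cross_properties
  for (key in names(properties)) {
    if (!key %in% allowed)
      bb_stop("unknown_property", "unknown cross property '%s' (allowed: %s)",
              key, paste(allowed, collapse = ", "))
    val <- properties[[key]]
    if (grepl("^number of", key)) {
      n <- suppressWarnings(as.numeric(val))
      if (is.na(n) || n < 0 || n != round(n))
        bb_stop("negative_count", "property '%s' must be a non-negative integer", key)
      val <- format(as.integer(n))
    } else if (grepl("date", key) && !is_iso_date(as.character(val))) {
      bb_stop("bad_date", "property '%s' must be an ISO-8601 date", key)
    }
    prev <- store$cross_props$cross_unique_id == cross_unique_id &
      store$cross_props$key == key
    if (any(prev)) store$cross_props <- store$cross_props[!prev, , drop = FALSE]
    store$cross_props <- df_append(store$cross_props, list(
      cross_unique_id = cross_unique_id, key = key, value = as.character(val)))
  }
  invisible(store)
}

#' Properties stored on a cross
#' @inheritParams set_cross_properties
#' @return named character vector
#' @export
cross_properties <- function(store, cross_unique_id) {
  find_cross(store, cross_unique_id)
  p <- store$cross_props[store$cross_props$cross_unique_id == cross_unique_id, ]
  stats::setNames(p$value, p$key)
}

#' Save progeny of a cross as new accessions with automatic pedigree
#'
#' Each progeny accession inherits the cross's female parent (as a pedigree
#' link), male parent (accession link or population text), and records the
#' cross type of origin. Default names are `<cross_unique_id>-P<i>`. The
#' whole batch is validated for name uniqueness first; a collision aborts
#' everything.
#'
#' @param store a store
#' @param cross_unique_id cross identifier
#' @param count number of progeny (ignored when `names` given)
#' @param names explicit progeny names
#' @param user acting account
#' @return character vector of created accession names
#' @export
create_progeny <- function(store, cross_unique_id, count = NULL, names = NULL,
                           user = "admin") {
  check_store(store)
  cr <- find_cross(store, cross_unique_id)
  require_auth(store, user, "create")
  if (is.null(names)) {
    if (is.null(count) || count < 1) bb_stop("bad_argument", "count must be >= 1")
    existing <- sum(store$accessions$female_parent_id ==
                      find_accession(store, cr$female_parent)$id &
                    grepl(paste0("^", cross_unique_id, "-P"), store$accessions$name),
                    na.rm = TRUE)
    names <- sprintf("%s-P%d", cross_unique_id, existing + seq_len(count))
  }
  keys <- normalize_name(names)
  taken <- c(store$accessions$norm, store$synonyms$norm)
  if (any(keys %in% taken) || anyDuplicated(keys))
    bb_stop("duplicate_name", "progeny name collision; batch aborted")
  fem <- find_accession(store, cr$female_parent)
  for (i in seq_along(names)) {
    store$accessions <- df_append(store$accessions, list(
      id = new_id(store), name = names[i], norm = keys[i],
      species = fem$species, female_parent_id = fem$id,
      male_parent = cr$male_parent, cross_type_of_origin = cr$cross_type,
      owner = user))
  }
  names
}

#' Render an accession's pedigree as a female/male string
#'
#' Depth 1 renders `<female>/<male>`, with `?` for an unknown parent (a
#' founder is `?/?`). Greater depths recurse into parents that themselves
#' have recorded parents, parenthesizing: e.g. `(C/D)/B`. The separator is
#' configurable via the instance config (`pedigree_separator`, default
#' `/`).
#'
#' @param store a store
#' @param accession accession name
#' @param depth recursion depth (>= 1)
#' @export
pedigree_string <- function(store, accession, depth = 1L) {
  check_store(store)
  acc <- find_accession(store, accession)
  if (is.null(acc)) bb_stop("unknown_accession", "no accession '%s'", accession)
  sep <- store$config$pedigree_separator %||% "/"
  render_parent <- function(name, d) {
    if (is.na(name)) return("?")
    p <- find_accession(store, name)
    if (is.null(p)) return(name)  # population-name male parent
    has_parents <- !is.na(p$female_parent_id) || !is.na(p$male_parent)
    if (d > 1 && has_parents) paste0("(", ped(p, d - 1L), ")") else p$name
  }
  ped <- function(a, d) {
    femname <- if (is.na(a$female_parent_id)) NA_character_ else
      store$accessions$name[match(a$female_parent_id, store$accessions$id)]
    paste0(render_parent(femname, d), sep, render_parent(a$male_parent, d))
  }
  if (depth < 1) bb_stop("bad_argument", "depth must be >= 1")
  ped(acc, as.integer(depth))
}

#' All crosses sharing a family name
#' @param store a store
#' @param family_name family label
#' @return data.frame of crosses (possibly empty), across all experiments
#' @export
crosses_by_family <- function(store, family_name) {
  check_store(store)
  store$crosses[!is.na(store$crosses$family_name) &
                store$crosses$family_name == family_name, , drop = FALSE]
}

#' Bulk-upload crosses from a CSV file
#'
#' Columns: `cross_unique_id,cross_type,female_parent,male_parent,
#' female_plot,male_plot,family_name` (only the first three are required).
#' Produces the same store state as creating the rows one by one.
#'
#' @param store a store
#' @param path CSV path
#' @param experiment crossing experiment receiving the crosses
#' @param user acting account
#' @return character vector of created cross ids
#' @export
upload_crosses <- function(store, path, experiment, user = "admin") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  req <- c("cross_unique_id", "cross_type", "female_parent")
  if (!all(req %in% names(df)))
    bb_stop("bad_file", "cross CSV needs columns %s", paste(req, collapse = ", "))
  opt <- function(col, i) {
    if (!col %in% names(df)) return(NULL)
    v <- df[[col]][i]
    if (is.na(v) || !nzchar(v)) NULL else v
  }
  for (i in seq_len(nrow(df))) {
    create_cross(store, experiment,
                 cross_unique_id = df$cross_unique_id[i],
                 cross_type = df$cross_type[i],
                 female = df$female_parent[i],
                 male = opt("male_parent", i),
                 female_unit = opt("female_plot", i),
                 male_unit = opt("male_plot", i),
                 family_name = opt("family_name", i) %||% NA_character_,
                 user = user)
  }
  df$cross_unique_id
}
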