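#' The three platform-wide role levels
#'
#' Role vocabulary for user accounts: `user` grants read-only access,
#' `submitter` may upload data and modify or delete their own uploads,
#' `curator` may modify anything. Breeding-program scoped roles use the
#' form `program:<name>` and gate create/update within that program.
#' @export
BB_ROLES <- c("user", "submitter", "curator")

#' Create an empty breedbox store
#'
#' A store is a single in-memory instance of the whole breeding database:
#' organisms, breeding programs, locations, users, accessions with synonyms
#' and passport properties, typed lists, datasets, trait variables, trials
#' and observation units, observations, crossing experiments and crosses,
#' genotyping protocols with per-sample dosage documents, plates, and saved
#' analysis results. It can be serialised to one portable JSON file with
#' [save_store()] and restored with [load_store()].
#'
#' The store is seeded with a bundled list of ~100 crop species (extendable
#' with `extra_organisms` or [add_organism()]) and an initial `admin`
#' account holding the curator role.
#'
#' @param extra_organisms optional data.frame with columns
#'   `name`, `genus`, `common_name` appended to the bundled organism list
#' @param config named list of instance settings; recognised keys:
#'   `cross_properties` (character vector of allowed cross annotation keys),
#'   `default_species` (species used when consolidation creates accessions),
#'   `wizard_max_steps` (default 4), `check_interval` (Westcott check column
#'   spacing, default 3), `pedigree_separator` (default "/")
#' @return an environment of class `bb_store`
#' @export
create_store <- function(extra_organisms = NULL, config = list()) {
  st <- new.env(parent = emptyenv())
  class(st) <- c("bb_store", "environment")

  org_path <- system.file("extdata", "organisms.tsv", package = "breedbox")
  orgs <- utils::read.delim(org_path, stringsAsFactors = FALSE)
  if (!is.null(extra_organisms)) {
    orgs <- rbind(orgs, extra_organisms[, c("name", "genus", "common_name")])
    orgs <- orgs[!duplicated(orgs$name), , drop = FALSE]
  }
  st$organisms <- orgs

  st$programs   <- empty_df(id = "integer", name = "character", description = "character")
  st$locations  <- empty_df(id = "integer", name = "character", country = "character")
  st$users      <- empty_df(username = "character")
  st$user_roles <- empty_df(username = "character", role = "character")

  st$accessions <- empty_df(
    id = "integer", name = "character", norm = "character",
    species = "character", female_parent_id = "integer",
    male_parent = "character", cross_type_of_origin = "character",
    owner = "character")
  st$synonyms        <- empty_df(accession_id = "integer", synonym = "character", norm = "character")
  st$accession_props <- empty_df(accession_id = "integer", key = "character", value = "character")

  st$lists         <- empty_df(id = "integer", name = "character", list_type = "character",
                               owner = "character", public = "logical")
  st$list_elements <- empty_df(list_id = "integer", pos = "integer", element = "character")
  st$datasets      <- list()

  st$traits <- empty_df(
    variable_id = "character", variable_name = "character", trait_name = "character",
    method_name = "character", scale_name = "character", scale_class = "character",
    minimum = "numeric", maximum = "numeric", categories = "character")

  st$trials <- empty_df(
    id = "integer", name = "character", breeding_program = "character",
    location = "character", year = "integer", trial_type = "character",
    design_type = "character", plot_width = "numeric", plot_length = "numeric",
    field_size = "numeric", owner = "character")
  st$units <- empty_df(
    id = "integer", name = "character", kind = "character", trial_id = "integer",
    accession_id = "integer", plot_number = "integer", block_number = "integer",
    rep_number = "integer", row = "integer", col = "integer",
    is_check = "logical", parent_id = "integer", treatment = "character")
  st$observations <- empty_df(
    unit_id = "integer", variable_id = "character", value = "character",
    timestamp = "character", collector = "character")
  st$trial_factors <- empty_df(trial_id = "integer", name = "character", value = "character")

  st$crossing_experiments <- empty_df(
    id = "integer", name = "character", breeding_program = "character",
    location = "character", year = "integer", description = "character",
    owner = "character")
  st$crosses <- empty_df(
    id = "integer", cross_unique_id = "character", experiment_id = "integer",
    cross_type = "character", female_parent = "character", male_parent = "character",
    female_unit = "character", male_unit = "character", family_name = "character",
    owner = "character")
  st$cross_props <- empty_df(cross_unique_id = "character", key = "character", value = "character")

  st$protocols <- list()   # name -> list(name, project, reference_genome, ploidy, markers, metadata)
  st$genotypes <- list()   # protocol name -> list(sample name -> named numeric dosage vector)
  st$plates    <- list()   # name -> list(name, format, wells)
  st$results   <- list()   # name -> bb_result

  defaults <- list(
    cross_properties = c("pollination date", "tag number", "number of flowers",
                         "number of bags", "number of fruits", "number of seeds"),
    default_species  = "Manihot esculenta",
    wizard_max_steps = 4L,
    check_interval   = 3L,
    pedigree_separator = "/"
  )
  defaults[names(config)] <- config
  st$config <- defaults

  st$counter <- 0L
  add_user(st, "admin", roles = c("user", "curator"))
  st
}

#' @export
print.bb_store <- function(x, ...) {
  cat("<breedbox store>\n")
  cat(sprintf("  organisms: %d | programs: %d | locations: %d | users: %d\n",
              nrow(x$organisms), nrow(x$programs), nrow(x$locations), nrow(x$users)))
  cat(sprintf("  accessions: %d (synonyms: %d) | lists: %d | datasets: %d\n",
              nrow(x$accessions), nrow(x$synonyms), nrow(x$lists), length(x$datasets)))
  cat(sprintf("  trials: %d | units: %d | observations: %d | traits: %d\n",
              nrow(x$trials), nrow(x$units), nrow(x$observations), nrow(x$traits)))
  cat(sprintf("  crossing experiments: %d | crosses: %d\n",
              nrow(x$crossing_experiments), nrow(x$crosses)))
  cat(sprintf("  genotyping protocols: %d | plates: %d | analysis results: %d\n",
              length(x$protocols), length(x$plates), length(x$results)))
  invisible(x)
}

new_id <- function(store) {
  store$counter <- store$counter + 1L
  store$counter
}

check_store <- function(store) {
  if (!inherits(store, "bb_store")) bb_stop("bad_argument", "not a bb_store")
  invisible(store)
}

#' Add an organism (species) to the store
#' @param store a [create_store()] store
#' @param name full species name, e.g. "Zea mays"
#' @param genus genus
#' @param common_name common name
#' @export
add_organism <- function(store, name, genus = strsplit(name, " ")[[1]][1], common_name = NA_character_) {
  check_store(store)
  assert_scalar_chr(name, "organism name")
  if (name %in% store$organisms$name) bb_stop("duplicate_name", "organism '%s' already exists", name)
  store$organisms <- df_append(store$organisms,
                               list(name = name, genus = genus, common_name = common_name))
  invisible(store)
}

#' Add a breeding program
#' @inheritParams add_organism
#' @param description free-text description
#' @export
add_breeding_program <- function(store, name, description = "") {
  check_store(store)
  assert_scalar_chr(name, "program name")
  if (name %in% store$programs$name) bb_stop("duplicate_name", "breeding program '%s' already exists", name)
  store$programs <- df_append(store$programs,
                              list(id = new_id(store), name = name, description = description))
  invisible(store)
}

#' Add a location
#' @inheritParams add_organism
#' @param country optional country name
#' @export
add_location <- function(store, name, country = NA_character_) {
  check_store(store)
  assert_scalar_chr(name, "location name")
  if (name %in% store$locations$name) bb_stop("duplicate_name", "location '%s' already exists", name)
  store$locations <- df_append(store$locations,
                               list(id = new_id(store), name = name, country = country))
  invisible(store)
}

#' Add a user account
#'
#' Every account implicitly holds the `user` role. Other roles must be one
#' of [BB_ROLES] or a `program:<breeding program>` role referencing an
#' existing program.
#'
#' @param store a store
#' @param username unique account name
#' @param roles character vector of roles
#' @export
add_user <- function(store, username, roles = "user") {
  check_store(store)
  assert_scalar_chr(username, "username")
  if (username %in% store$users$username) bb_stop("duplicate_name", "user '%s' already exists", username)
  roles <- union("user", roles)
  for (r in roles) {
    if (r %in% BB_ROLES) next
    if (startsWith(r, "program:")) {
      prog <- sub("^program:", "", r)
      if (!prog %in% store$programs$name)
        bb_stop("unknown_program", "program role '%s' references unknown breeding program", r)
    } else {
      bb_stop("unknown_role", "unknown role '%s' (allowed: %s, program:<name>)",
              r, paste(BB_ROLES, collapse = ", "))
    }
  }
  store$users <- df_append(store$users, list(username = username))
  for (r in roles)
    store$user_roles <- df_append(store$user_roles, list(username = username, role = r))
  invisible(store)
}

#' Add a role to an existing user
#' @inheritParams add_user
#' @param role a single role
#' @export
grant_role <- function(store, username, role) {
  check_store(store)
  if (!username %in% store$users$username) bb_stop("unknown_user", "no user '%s'", username)
  if (!(role %in% BB_ROLES || startsWith(role, "program:")))
    bb_stop("unknown_role", "unknown role '%s'", role)
  if (startsWith(role, "program:") &&
      !sub("^program:", "", role) %in% store$programs$name)
    bb_stop("unknown_program", "program role '%s' references unknown breeding program", role)
  has <- store$user_roles$username == username & store$user_roles$role == role
  if (!any(has))
    store$user_roles <- df_append(store$user_roles, list(username = username, role = role))
  invisible(store)
}

user_roles <- function(store, username) {
  if (!username %in% store$users$username) bb_stop("unknown_user", "no user '%s'", username)
  store$user_roles$role[store$user_roles$username == username]
}

#' Authorization decision
#'
#' Pure function of the user's roles and the object's ownership, following
#' the platform's three-level model: the `user` role is read-only; a
#' `submitter` may create data and may update or delete only data they
#' themselves own; a `curator` may do anything. When `object_program` is
#' given, create and update/delete by a submitter additionally require the
#' matching `program:<name>` role.
#'
#' @param store a store
#' @param username acting account
#' @param action one of `"read"`, `"create"`, `"update"`, `"delete"`
#' @param object_owner username owning the object acted on (for
#'   update/delete); ignored for read/create
#' @param object_program optional breeding program the object belongs to
#' @return `TRUE` (allow) or `FALSE` (deny)
#' @export
authorize <- function(store, username, action,
                      object_owner = NULL, object_program = NULL) {
  check_store(store)
  if (!action %in% c("read", "create", "update", "delete"))
    bb_stop("unknown_action", "unknown action '%s'", action)
  roles <- user_roles(store, username)
  if ("curator" %in% roles) return(TRUE)
  if (action == "read") return(TRUE)
  if (!"submitter" %in% roles) return(FALSE)
  if (!is.null(object_program) &&
      !paste0("program:", object_program) %in% roles) return(FALSE)
  if (action == "create") return(TRUE)
  # update / delete: submitters touch only their own uploads
  !is.null(object_owner) && identical(object_owner, username)
}

require_auth <- function(store, username, action, object_owner = NULL, object_program = NULL) {
  if (!authorize(store, username, action, object_owner, object_program))
    bb_stop("not_authorized", "user '%s' is not authorized to %s", username, action)
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# Persistence: the whole instance serialises to one JSON file.

#' Save a store to a single portable JSON file
#' @param store a store
#' @param path file path
#' @export
save_store <- function(store, path) {
  check_store(store)
  payload <- list(
    format = "breedbox-store", version = 1L, counter = store$counter,
    config = store$config,
    organisms = store$organisms, programs = store$programs,
    locations = store$locations, users = store$users, user_roles = store$user_roles,
    accessions = store$accessions, synonyms = store$synonyms,
    accession_props = store$accession_props,
    lists = store$lists, list_elements = store$list_elements,
    datasets = store$datasets,
    traits = store$traits, trials = store$trials, units = store$units,
    observations = store$observations, trial_factors = store$trial_factors,
    crossing_experiments = store$crossing_experiments, crosses = store$crosses,
    cross_props = store$cross_props,
    protocols = store$protocols,
    genotypes = lapply(store$genotypes, function(p) lapply(p, as.list)),
    plates = lapply(store$plates, function(p) { p$wells <- as.list(p$wells); p }),
    results = lapply(store$results, function(r) {
      r <- unclass(r); r$values <- as.list(r$values); r
    })
  )
  json <- jsonlite::toJSON(payload, dataframe = "columns", na = "null",
                           auto_unbox = TRUE, digits = NA, pretty = FALSE)
  writeLines(json, path)
  invisible(path)
}

restore_df <- function(cols, template) {
  if (length(cols) == 0 || length(cols[[1]]) == 0) return(template)
  out <- as.data.frame(lapply(cols, unlist), stringsAsFactors = FALSE)
  for (nm in names(template)) {
    cl <- class(template[[nm]])[1]
    out[[nm]] <- switch(cl,
      integer = as.integer(out[[nm]]), numeric = as.numeric(out[[nm]]),
      logical = as.logical(out[[nm]]), as.character(out[[nm]]))
  }
  out[, names(template), drop = FALSE]
}

#' Load a store from a JSON file written by [save_store()]
#' @param path file path
#' @return a `bb_store`
#' @export
load_store <- function(path) {
  raw <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (!identical(raw$format, "breedbox-store"))
    bb_stop("bad_store_file", "'%s' is not a breedbox store file", path)
  st <- create_store()
  for (tbl in c("programs", "locations", "users", "user_roles", "accessions",
                "synonyms", "accession_props", "lists", "list_elements", "traits",
                "trials", "units", "observations", "trial_factors",
                "crossing_experiments", "crosses", "cross_props")) {
    st[[tbl]] <- restore_df(raw[[tbl]], st[[tbl]])
  }
  st$organisms <- restore_df(raw$organisms, st$organisms[0, ])
  st$config <- raw$config
  st$config$wizard_max_steps <- as.integer(st$config$wizard_max_steps)
  st$config$check_interval <- as.integer(st$config$check_interval)
  st$config$cross_properties <- unlist(st$config$cross_properties)
  st$counter <- as.integer(raw$counter)
  st$datasets <- lapply(raw$datasets, function(d) {
    d$selection <- lapply(d$selection, unlist)
    d
  })
  st$protocols <- lapply(raw$protocols, function(p) {
    p$markers <- restore_df(p$markers, empty_df(
      name = "character", chrom = "character", pos = "integer",
      ref_allele = "character", alt_allele = "character"))
    p$ploidy <- as.integer(p$ploidy)
    p$project <- if (is.null(p$project)) NA_character_ else p$project
    p
  })
  st$genotypes <- lapply(raw$genotypes, function(p) {
    lapply(p, function(s) {
      v <- vapply(s, function(x) if (is.null(x)) NA_real_ else as.numeric(x), numeric(1))
      v
    })
  })
  st$plates <- lapply(raw$plates, function(p) {
    p$format <- as.integer(p$format)
    p$wells <- unlist(p$wells) %||% character(0)
    p
  })
  st$results <- lapply(raw$results, function(r) {
    r$values <- vapply(r$values, function(x) if (is.null(x)) NA_real_ else as.numeric(x), numeric(1))
    class(r) <- "bb_result"
    r
  })
  st
}
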