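# Germplasm registry: accessions, synonyms, passport properties.

# MCPD-style passport descriptor columns accepted on bulk upload.
MCPD_COLUMNS <- c("variety", "donor", "donor_institute", "donor_PUI",
                  "country_of_origin", "institute_code", "institute_name",
                  "notes", "accession_number", "PUI")

#' Resolve a name or synonym to its accession record
#'
#' Matching is exact after [normalize_name()]; synonyms resolve to the
#' accession carrying them.
#'
#' @param store a store
#' @param name accession name or synonym
#' @return a one-row list (`id`, `name`, `norm`, `species`, ...) or `NULL`
#' @export
find_accession <- function(store, name) {
  check_store(store)
  key <- normalize_name(name)
  i <- match(key, store$accessions$norm)
  if (is.na(i)) {
    j <- match(key, store$synonyms$norm)
    if (is.na(j)) return(NULL)
    i <- match(store$synonyms$accession_id[j], store$accessions$id)
  }
  as.list(store$accessions[i, , drop = FALSE])
}

#' Add accessions in bulk with per-entry accept/reject semantics
#'
#' Each entry needs a unique name (uniqueness is global over all accession
#' names *and* synonyms, on normalized keys) and a species present in the
#' organism table. Valid entries are stored; invalid ones are returned with
#' a machine-readable reason (`duplicate_name`, `duplicate_synonym`,
#' `unknown_species`, `empty_name`). A duplicate within the submitted batch
#' rejects the second occurrence.
#'
#' @param store a store
#' @param entries data.frame with columns `name`, `species`, and optionally
#'   `synonyms` (pipe-separated or a list column) plus any of the passport
#'   columns `variety`, `donor`, `donor_institute`, `donor_PUI`,
#'   `country_of_origin`, `institute_code`, `institute_name`, `notes`,
#'   `accession_number`, `PUI`
#' @param user acting account (must be authorized to create)
#' @return list with `created` (data.frame id/name) and `rejected`
#'   (data.frame name/reason); the two partition the input exactly
#' @export
add_accessions <- function(store, entries, user = "admin") {
  check_store(store)
  require_auth(store, user, "create")
  if (!all(c("name", "species") %in% names(entries)))
    bb_stop("bad_argument", "entries need 'name' and 'species' columns")
  created <- empty_df(id = "integer", name = "character")
  rejected <- empty_df(name = "character", reason = "character")
  taken <- c(store$accessions$norm, store$synonyms$norm)
  prop_cols <- intersect(MCPD_COLUMNS, names(entries))
  for (i in seq_len(nrow(entries))) {
    nm <- entries$name[i]
    syns <- entry_synonyms(entries, i)
    key <- tryCatch(normalize_name(nm), bb_empty_name = function(e) NA_character_)
    if (is.na(key)) {
      rejected <- df_append(rejected, list(name = nm, reason = "empty_name")); next
    }
    skeys <- tryCatch(normalize_name(syns), bb_empty_name = function(e) NULL)
    if (length(syns) && is.null(skeys)) {
      rejected <- df_append(rejected, list(name = nm, reason = "empty_name")); next
    }
    skeys <- skeys %||% character(0)
    # synonyms collapsing to one key keep their first spelling only
    keep <- !duplicated(skeys)
    syns <- syns[keep]; skeys <- skeys[keep]
    if (key %in% taken) {
      rejected <- df_append(rejected, list(name = nm, reason = "duplicate_name")); next
    }
    # synonyms normalization-equal to the entry's own name are allowed (they
    # resolve to the same accession); anything else must be globally free
    foreign <- setdiff(skeys, key)
    if (any(foreign %in% taken)) {
      rejected <- df_append(rejected, list(name = nm, reason = "duplicate_synonym")); next
    }
    if (!entries$species[i] %in% store$organisms$name) {
      rejected <- df_append(rejected, list(name = nm, reason = "unknown_species")); next
    }
    id <- new_id(store)
    store$accessions <- df_append(store$accessions, list(
      id = id, name = nm, norm = key, species = entries$species[i],
      female_parent_id = NA_integer_, male_parent = NA_character_,
      cross_type_of_origin = NA_character_, owner = user))
    for (k in seq_along(skeys))
      store$synonyms <- df_append(store$synonyms, list(
        accession_id = id, synonym = syns[k], norm = skeys[k]))
    for (pc in prop_cols) {
      v <- entries[[pc]][i]
      if (!is.na(v) && nzchar(v))
        store$accession_props <- df_append(store$accession_props, list(
          accession_id = id, key = pc, value = as.character(v)))
    }
    taken <- c(taken, key, skeys)
    created <- df_append(created, list(id = id, name = nm))
  }
  list(created = created, rejected = rejected)
}

entry_synonyms <- function(entries, i) {
  if (!"synonyms" %in% names(entries)) return(character(0))
  s <- entries$synonyms[[i]]
  if (is.null(s) || all(is.na(s))) return(character(0))
  if (length(s) == 1 && grepl("|", s, fixed = TRUE)) s <- strsplit(s, "|", fixed = TRUE)[[1]]
  s <- trimws(as.character(s))
  s[nzchar(s)]
}

#' Attach a synonym to an accession
#'
#' The synonym participates in global name uniqueness; lookups by the
#' synonym resolve to the accession. Adding the accession's own name
#' (after normalization) is a warning no-op.
#'
#' @param store a store
#' @param accession_name name (or synonym) of an existing accession
#' @param synonym synonym to attach
#' @param user acting account
#' @export
add_synonym <- function(store, accession_name, synonym, user = "admin") {
  check_store(store)
  acc <- find_accession(store, accession_name)
  if (is.null(acc)) bb_stop("unknown_accession", "no accession '%s'", accession_name)
  require_auth(store, user, "update", object_owner = acc$owner)
  key <- normalize_name(synonym)
  own <- store$synonyms[store$synonyms$accession_id == acc$id, ]
  if (identical(synonym, acc$name) || synonym %in% own$synonym ||
      (key %in% own$norm)) {
    warning(sprintf("synonym '%s' adds nothing to accession '%s'; ignored",
                    synonym, acc$name))
    return(invisible(acc))
  }
  other <- find_accession(store, synonym)
  if (!is.null(other) && other$id != acc$id)
    bb_stop("duplicate_synonym", "'%s' already names accession '%s'", synonym, other$name)
  store$synonyms <- df_append(store$synonyms, list(
    accession_id = acc$id, synonym = synonym, norm = key))
  invisible(find_accession(store, acc$name))
}

#' Rename an accession, preserving its identity and links
#'
#' Identity is by surrogate id, so every trial plot, cross and genotype
#' record linked to the accession still resolves after the rename. The new
#' name must pass global uniqueness (excluding the accession's own current
#' name and synonyms). Renaming to the current name is a no-op.
#'
#' @param store a store
#' @param old_name current name
#' @param new_name new name
#' @param user acting account
#' @export
rename_accession <- function(store, old_name, new_name, user = "admin") {
  check_store(store)
  acc <- find_accession(store, old_name)
  if (is.null(acc)) bb_stop("unknown_accession", "no accession '%s'", old_name)
  require_auth(store, user, "update", object_owner = acc$owner)
  key <- normalize_name(new_name)
  if (identical(key, acc$norm)) {
    i <- match(acc$id, store$accessions$id)
    store$accessions$name[i] <- new_name
    return(invisible(find_accession(store, new_name)))
  }
  clash <- find_accession(store, new_name)
  if (!is.null(clash) && clash$id != acc$id)
    bb_stop("duplicate_name", "'%s' already in use by accession '%s'", new_name, clash$name)
  i <- match(acc$id, store$accessions$id)
  store$accessions$name[i] <- new_name
  store$accessions$norm[i] <- key
  invisible(find_accession(store, new_name))
}

#' Delete an accession (restrict policy)
#'
#' Refused while any observation unit, cross (as parent), progeny pedigree
#' link, list element or stored genotype references the accession.
#'
#' @inheritParams add_synonym
#' @export
delete_accession <- function(store, accession_name, user = "admin") {
  check_store(store)
  acc <- find_accession(store, accession_name)
  if (is.null(acc)) bb_stop("unknown_accession", "no accession '%s'", accession_name)
  require_auth(store, user, "delete", object_owner = acc$owner)
  if (any(store$units$accession_id == acc$id))
    bb_stop("referenced", "accession '%s' is used by trial observation units", acc$name)
  if (any(store$crosses$female_parent == acc$name, na.rm = TRUE) ||
      any(store$crosses$male_parent == acc$name, na.rm = TRUE))
    bb_stop("referenced", "accession '%s' is a parent in stored crosses", acc$name)
  if (any(store$accessions$female_parent_id == acc$id, na.rm = TRUE) ||
      any(store$accessions$male_parent == acc$name, na.rm = TRUE))
    bb_stop("referenced", "accession '%s' appears in pedigrees", acc$name)
  if (any(vapply(store$genotypes, function(p) acc$name %in% names(p), logical(1))))
    bb_stop("referenced", "accession '%s' has stored genotypes", acc$name)
  store$accession_props <- store$accession_props[store$accession_props$accession_id != acc$id, ]
  store$synonyms <- store$synonyms[store$synonyms$accession_id != acc$id, ]
  store$accessions <- store$accessions[store$accessions$id != acc$id, ]
  invisible(store)
}

#' List passport properties of an accession
#' @inheritParams add_synonym
#' @return named character vector
#' @export
accession_properties <- function(store, accession_name) {
  acc <- find_accession(store, accession_name)
  if (is.null(acc)) bb_stop("unknown_accession", "no accession '%s'", accession_name)
  p <- store$accession_props[store$accession_props$accession_id == acc$id, ]
  stats::setNames(p$value, p$key)
}

#' Synonyms of an accession
#' @inheritParams add_synonym
#' @export
accession_synonyms <- function(store, accession_name) {
  acc <- find_accession(store, accession_name)
  if (is.null(acc)) bb_stop("unknown_accession", "no accession '%s'", accession_name)
  store$synonyms$synonym[store$synonyms$accession_id == acc$id]
}

#' Read an accession bulk-upload CSV
#'
#' Expected header: `accession_name,species_name,synonyms,` followed by the
#' MCPD passport columns (`variety,donor,donor_institute,donor_PUI,
#' country_of_origin,institute_code,institute_name,notes,accession_number,
#' PUI`). Synonyms are pipe-separated. Returns an `entries` data.frame for
#' [add_accessions()].
#'
#' @param path CSV path
#' @export
read_accession_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  if (!all(c("accession_name", "species_name") %in% names(df)))
    bb_stop("bad_file", "accession CSV needs accession_name and species_name columns")
  out <- data.frame(name = df$accession_name, species = df$species_name,
                    stringsAsFactors = FALSE)
  if ("synonyms" %in% names(df)) out$synonyms <- df$synonyms
  for (pc in intersect(MCPD_COLUMNS, names(df))) out[[pc]] <- df[[pc]]
  out
}
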