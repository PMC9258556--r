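# Typed lists and list validation.

LIST_TYPES <- c("accessions", "trials", "traits", "years", "locations",
                "breeding_programs", "plots")

#' Create a typed list
#'
#' Lists are ordered collections of text elements naming database objects;
#' the type is fixed at creation and duplicate elements are rejected. Lists
#' are private to their owner until shared with [set_list_public()].
#'
#' @param store a store
#' @param name list name, unique per owner
#' @param list_type one of `accessions`, `trials`, `traits`, `years`,
#'   `locations`, `breeding_programs`, `plots`
#' @param elements character vector of element names
#' @param owner owning account
#' @param public share immediately
#' @return the list id (invisibly)
#' @export
create_list <- function(store, name, list_type, elements, owner = "admin",
                        public = FALSE) {
  check_store(store)
  assert_scalar_chr(name, "list name")
  if (!list_type %in% LIST_TYPES)
    bb_stop("unknown_list_type", "unknown list type '%s' (allowed: %s)",
            list_type, paste(LIST_TYPES, collapse = ", "))
  if (!owner %in% store$users$username) bb_stop("unknown_user", "no user '%s'", owner)
  elements <- as.character(elements)
  if (anyDuplicated(elements))
    bb_stop("duplicate_element", "list elements must be unique")
  if (any(store$lists$name == name & store$lists$owner == owner))
    bb_stop("duplicate_name", "user '%s' already has a list '%s'", owner, name)
  id <- new_id(store)
  store$lists <- df_append(store$lists, list(
    id = id, name = name, list_type = list_type, owner = owner, public = public))
  for (i in seq_along(elements))
    store$list_elements <- df_append(store$list_elements, list(
      list_id = id, pos = i, element = elements[i]))
  invisible(id)
}

find_list <- function(store, name, owner) {
  i <- which(store$lists$name == name & store$lists$owner == owner)
  if (!length(i)) bb_stop("unknown_list", "user '%s' has no list '%s'", owner, name)
  as.list(store$lists[i, , drop = FALSE])
}

#' Elements of a typed list, in order
#' @param store a store
#' @param name list name
#' @param owner list owner
#' @export
list_elements <- function(store, name, owner = "admin") {
  l <- find_list(store, name, owner)
  e <- store$list_elements[store$list_elements$list_id == l$id, ]
  e$element[order(e$pos)]
}

#' Share or unshare a list
#'
#' Public lists are visible to all users; unsharing makes them private to
#' the owner again.
#'
#' @inheritParams list_elements
#' @param public logical flag
#' @export
set_list_public <- function(store, name, owner, public = TRUE) {
  l <- find_list(store, name, owner)
  store$lists$public[store$lists$id == l$id] <- public
  invisible(store)
}

#' Lists visible to a user (their own plus all public lists)
#' @param store a store
#' @param username viewing account
#' @return data.frame of list metadata
#' @export
visible_lists <- function(store, username) {
  check_store(store)
  store$lists[store$lists$owner == username | store$lists$public, , drop = FALSE]
}

#' Validate a list against the store
#'
#' Accession lists go through the full name-resolution partition of
#' [validate_names()] (so elements matching only via synonym are still
#' valid, but flagged); every other type is an exact-name existence check
#' against the corresponding dimension. A list is valid iff no element is
#' absent.
#'
#' @inheritParams list_elements
#' @return list with `valid` (logical), `absent` (character vector), and
#'   for accession lists the full `report` from [validate_names()]
#' @export
validate_list <- function(store, name, owner = "admin") {
  l <- find_list(store, name, owner)
  els <- list_elements(store, name, owner)
  if (l$list_type == "accessions") {
    rep <- validate_names(els, store)
    absent <- c(rep$absent, vapply(rep$fuzzy, function(r) r$query, character(1)))
    return(list(valid = length(absent) == 0, absent = absent, report = rep))
  }
  known <- dimension_values(store, l$list_type)
  absent <- setdiff(els, known)
  list(valid = length(absent) == 0, absent = absent, report = NULL)
}
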