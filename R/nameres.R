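#' Normalize a germplasm name to its canonical matching key
#'
#' Uppercases and strips the characters that cause most germplasm naming
#' inconsistencies: spaces, dots, dashes, underscores and slashes. All
#' other characters are preserved. The function is idempotent and
#' vectorised. Global accession/synonym uniqueness and all approximate
#' matching operate on these keys, so "Tx 303" and "TX303" collide.
#'
#' @param raw character vector of raw names
#' @return character vector of canonical keys
#' @export
normalize_name <- function(raw) {
  if (!is.character(raw)) raw <- as.character(raw)
  out <- toupper(gsub("[ ./_-]", "", raw))
  if (any(!nzchar(out) | is.na(out)))
    bb_stop("empty_name", "name empty after normalization: %s",
            paste(sprintf("'%s'", raw[!nzchar(out) | is.na(out)]), collapse = ", "))
  out
}

# All matchable strings in a store: accession names and synonyms, each
# mapped to the accession it resolves to.
name_universe <- function(store) {
  acc <- store$accessions
  uni <- data.frame(
    string = acc$name, accession = acc$name,
    matched_via = rep("name", nrow(acc)),
    norm = acc$norm, stringsAsFactors = FALSE)
  if (nrow(store$synonyms)) {
    syn <- store$synonyms
    uni <- rbind(uni, data.frame(
      string = syn$synonym,
      accession = acc$name[match(syn$accession_id, acc$id)],
      matched_via = "synonym", norm = syn$norm, stringsAsFactors = FALSE))
  }
  uni
}

#' Approximate matching of germplasm names
#'
#' For each query, finds every accession name or synonym whose Levenshtein
#' distance to the query -- computed on [normalize_name()] keys -- is at
#' most `max_distance`. Candidates are ranked by ascending distance, ties
#' broken lexicographically by accession name; an accession matched through
#' both its name and a synonym is reported once at its best distance.
#' The similarity score is `1 - distance / max(nchar(query key),
#' nchar(candidate key))`, so score 1 means equal after normalization.
#'
#' @param queries character vector of names to look up
#' @param universe a `bb_store` (names + synonyms) or a character vector of
#'   candidate names
#' @param max_distance maximum edit distance (default 2)
#' @return a list of match reports, one per query: each is a list with
#'   `query` and a data.frame `candidates` with columns
#'   `name`, `matched_via`, `distance`, `score`
#' @export
match_names <- function(queries, universe, max_distance = 2L) {
  if (inherits(universe, "bb_store")) {
    uni <- name_universe(universe)
  } else {
    uni <- data.frame(string = as.character(universe),
                      accession = as.character(universe),
                      matched_via = "name", stringsAsFactors = FALSE)
    uni$norm <- normalize_name(uni$string)
  }
  if (nrow(uni) == 0) bb_stop("empty_universe", "no names to match against")
  qn <- normalize_name(queries)
  D <- utils::adist(qn, uni$norm)  # Levenshtein, unit costs
  lapply(seq_along(queries), function(i) {
    hit <- which(D[i, ] <= max_distance)
    cand <- data.frame(
      name = uni$accession[hit], matched_via = uni$matched_via[hit],
      distance = as.integer(D[i, hit]), stringsAsFactors = FALSE)
    cand$score <- 1 - cand$distance /
      pmax(nchar(qn[i]), nchar(uni$norm[hit]))
    # best hit per accession (prefer direct name on equal distance)
    cand <- cand[order(cand$distance, cand$matched_via, cand$name), , drop = FALSE]
    cand <- cand[!duplicated(cand$name), , drop = FALSE]
    cand <- cand[order(cand$distance, cand$name), , drop = FALSE]
    rownames(cand) <- NULL
    list(query = queries[i], candidates = cand)
  })
}

#' Partition a list of names against the store
#'
#' The list-validation workflow: each input name lands in exactly one of
#' four buckets. `exact` -- equal (after normalization) to an accession
#' name; `by_synonym` -- equal to a stored synonym; `fuzzy` -- no exact hit
#' but at least one candidate within `max_distance`; `absent` -- otherwise.
#'
#' @param names character vector of candidate names
#' @param store a store
#' @param max_distance edit-distance cutoff for the fuzzy bucket
#' @return list with elements `exact`, `by_synonym`, `absent` (character
#'   vectors of input names) and `fuzzy` (list of match reports as in
#'   [match_names()])
#' @export
validate_names <- function(names, store, max_distance = 2L) {
  check_store(store)
  out <- list(exact = character(0), by_synonym = character(0),
              fuzzy = list(), absent = character(0))
  if (length(names) == 0) return(out)
  uni <- name_universe(store)
  qn <- normalize_name(names)
  reports <- if (nrow(uni)) match_names(names, store, max_distance) else
    lapply(names, function(q) list(query = q, candidates = NULL))
  for (i in seq_along(names)) {
    # a raw string stored verbatim as a synonym is a synonym hit even when
    # it also normalizes to the accession's own name
    if (names[i] %in% uni$string[uni$matched_via == "synonym"]) {
      out$by_synonym <- c(out$by_synonym, names[i])
    } else if (qn[i] %in% uni$norm[uni$matched_via == "name"]) {
      out$exact <- c(out$exact, names[i])
    } else if (qn[i] %in% uni$norm[uni$matched_via == "synonym"]) {
      out$by_synonym <- c(out$by_synonym, names[i])
    } else if (!is.null(reports[[i]]$candidates) && nrow(reports[[i]]$candidates) > 0) {
      out$fuzzy <- c(out$fuzzy, list(reports[[i]]))
    } else {
      out$absent <- c(out$absent, names[i])
    }
  }
  out
}

#' Apply synonym-consolidation decisions atomically
#'
#' Executes the outcome of a name-review workflow. Each decision is a list
#' with `name` plus `action`: `"create_new"` (create an accession, species
#' from `species` or the instance default), `"add_as_synonym_of"` (attach
#' `name` as a synonym of accession `target`), or `"skip"`. The whole batch
#' is validated first; if any decision would violate uniqueness or
#' reference a missing accession, nothing is applied.
#'
#' @param store a store
#' @param decisions list of decision lists (fields `name`, `action`, and
#'   `target`/`species` as required)
#' @param user acting account
#' @return report list with `created` (names), `synonyms_added`
#'   (data.frame name/target), `skipped` (names)
#' @export
apply_consolidation <- function(store, decisions, user = "admin") {
  check_store(store)
  require_auth(store, user, "create")
  taken <- c(store$accessions$norm, store$synonyms$norm)
  pending <- character(0)
  for (d in decisions) {
    act <- d$action %||% bb_stop("bad_argument", "decision without action")
    if (act == "skip") next
    key <- normalize_name(d$name)
    if (act == "create_new") {
      if (key %in% c(taken, pending))
        bb_stop("duplicate_name", "consolidation aborted: '%s' collides", d$name)
      sp <- d$species %||% store$config$default_species
      if (!sp %in% store$organisms$name)
        bb_stop("unknown_species", "consolidation aborted: unknown species '%s'", sp)
      pending <- c(pending, key)
    } else if (act == "add_as_synonym_of") {
      tgt <- find_accession(store, d$target)
      if (is.null(tgt))
        bb_stop("unknown_accession", "consolidation aborted: no accession '%s'", d$target)
      if (key %in% pending || (key %in% taken && !identical(key, tgt$norm)))
        bb_stop("duplicate_synonym", "consolidation aborted: '%s' collides", d$name)
      if (!identical(key, tgt$norm)) pending <- c(pending, key)
    } else {
      bb_stop("bad_argument", "unknown consolidation action '%s'", act)
    }
  }
  report <- list(created = character(0),
                 synonyms_added = empty_df(name = "character", target = "character"),
                 skipped = character(0))
  for (d in decisions) {
    if (d$action == "skip") {
      report$skipped <- c(report$skipped, d$name)
    } else if (d$action == "create_new") {
      sp <- d$species %||% store$config$default_species
      add_accessions(store, data.frame(name = d$name, species = sp,
                                       stringsAsFactors = FALSE), user = user)
      report$created <- c(report$created, d$name)
    } else {
      acc_name <- find_accession(store, d$target)$name
      suppressWarnings(add_synonym(store, acc_name, d$name, user = user))
      report$synonyms_added <- df_append(report$synonyms_added,
                                         list(name = d$name, target = acc_name))
    }
  }
  report
}
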