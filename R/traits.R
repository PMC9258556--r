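# Crop-ontology style trait variables (trait + method + scale) and value
# validation against their scales.

SCALE_CLASSES <- c("numeric", "categorical", "date", "text")

#' Load a trait dictionary TSV
#'
#' Expected tab-separated columns: `variable_id`, `variable_name`,
#' `trait_name`, `method_name`, `scale_name`, `scale_class`, `categories`
#' (pipe-separated, required for categorical scales), `minimum`, `maximum`
#' (optional numeric bounds). Re-loading an existing `variable_id` updates
#' it in place.
#'
#' @param store a store
#' @param path TSV path
#' @return data.frame of the variables loaded
#' @export
load_trait_dictionary <- function(store, path) {
  check_store(store)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  req <- c("variable_id", "variable_name", "trait_name", "method_name",
           "scale_name", "scale_class")
  miss <- setdiff(req, names(df))
  if (length(miss)) bb_stop("bad_file", "trait dictionary missing columns: %s",
                            paste(miss, collapse = ", "))
  for (opt in c("categories", "minimum", "maximum"))
    if (!opt %in% names(df)) df[[opt]] <- NA_character_
  for (i in seq_len(nrow(df))) {
    add_trait_variable(store,
      variable_id = df$variable_id[i], variable_name = df$variable_name[i],
      trait_name = df$trait_name[i], method_name = df$method_name[i],
      scale_name = df$scale_name[i], scale_class = df$scale_class[i],
      categories = if (is.na(df$categories[i]) || !nzchar(df$categories[i])) NULL
                   else strsplit(df$categories[i], "|", fixed = TRUE)[[1]],
      minimum = suppressWarnings(as.numeric(df$minimum[i])),
      maximum = suppressWarnings(as.numeric(df$maximum[i])))
  }
  store$traits[store$traits$variable_id %in% df$variable_id, , drop = FALSE]
}

#' Define (or update) a single trait variable
#'
#' @param store a store
#' @param variable_id stable ontology-style identifier (e.g.
#'   `CO_334:0000092`)
#' @param variable_name unique variable name used in collection files
#' @param trait_name,method_name,scale_name the trait/method/scale triple
#' @param scale_class one of `numeric`, `categorical`, `date`, `text`
#' @param categories ordered character vector (categorical scales only)
#' @param minimum,maximum optional numeric bounds (numeric scales only)
#' @export
add_trait_variable <- function(store, variable_id, variable_name,
                               trait_name = variable_name, method_name = "measurement",
                               scale_name = "scale", scale_class = "numeric",
                               categories = NULL, minimum = NA_real_, maximum = NA_real_) {
  check_store(store)
  if (!scale_class %in% SCALE_CLASSES)
    bb_stop("bad_scale", "unknown scale class '%s'", scale_class)
  if (scale_class == "categorical" && length(categories) == 0)
    bb_stop("bad_scale", "categorical variable '%s' needs categories", variable_id)
  if (!is.na(minimum) && !is.na(maximum) && minimum > maximum)
    bb_stop("bad_scale", "variable '%s': minimum %s > maximum %s",
            variable_id, minimum, maximum)
  row <- list(variable_id = variable_id, variable_name = variable_name,
              trait_name = trait_name, method_name = method_name,
              scale_name = scale_name, scale_class = scale_class,
              minimum = as.numeric(minimum), maximum = as.numeric(maximum),
              categories = if (length(categories)) paste(categories, collapse = "|")
                           else NA_character_)
  i <- match(variable_id, store$traits$variable_id)
  if (is.na(i)) {
    store$traits <- df_append(store$traits, row)
  } else {
    for (nm in names(row)) store$traits[[nm]][i] <- row[[nm]]
  }
  invisible(store)
}

find_variable <- function(store, id_or_name) {
  i <- match(id_or_name, store$traits$variable_id)
  if (is.na(i)) i <- match(id_or_name, store$traits$variable_name)
  if (is.na(i)) bb_stop("unknown_variable", "no trait variable '%s'", id_or_name)
  as.list(store$traits[i, , drop = FALSE])
}

variable_categories <- function(variable) {
  if (is.na(variable$categories)) character(0)
  else strsplit(variable$categories, "|", fixed = TRUE)[[1]]
}

#' Validate a phenotype value against a variable's scale
#'
#' Numeric scales require a parseable real within `[minimum, maximum]`
#' where bounds are present; categorical scales require membership in the
#' category list; date scales require ISO-8601 dates; text accepts
#' anything non-missing. Violations are returned, not raised.
#'
#' @param store a store
#' @param variable variable id or name
#' @param value value as text
#' @return list with `ok` (logical) and, when not ok, `reason` (one of
#'   `empty`, `not_numeric`, `below_minimum`, `above_maximum`,
#'   `out_of_categories`, `bad_date`)
#' @export
validate_value <- function(store, variable, value) {
  v <- find_variable(store, variable)
  value <- as.character(value)
  if (length(value) != 1 || is.na(value) || !nzchar(trimws(value)))
    return(list(ok = FALSE, reason = "empty"))
  value <- trimws(value)
  switch(v$scale_class,
    numeric = {
      x <- suppressWarnings(as.numeric(value))
      if (is.na(x)) return(list(ok = FALSE, reason = "not_numeric"))
      if (!is.na(v$minimum) && x < v$minimum) return(list(ok = FALSE, reason = "below_minimum"))
      if (!is.na(v$maximum) && x > v$maximum) return(list(ok = FALSE, reason = "above_maximum"))
      list(ok = TRUE)
    },
    categorical = {
      if (!value %in% variable_categories(v))
        return(list(ok = FALSE, reason = "out_of_categories"))
      list(ok = TRUE)
    },
    date = {
      if (!is_iso_date(value)) return(list(ok = FALSE, reason = "bad_date"))
      list(ok = TRUE)
    },
    text = list(ok = TRUE))
}
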