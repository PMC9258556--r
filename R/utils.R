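# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a structured breedbox error
#'
#' All operational failures carry a machine-readable condition class
#' `bb_<code>` (e.g. `bb_duplicate_name`) so callers and tests can react to
#' the reason, not the message text.
#'
#' @param code short snake_case reason code
#' @param msg sprintf-style message
#' @param ... sprintf arguments
#' @noRd
bb_stop <- function(code, msg, ...) {
  stop(structure(
    class = c(paste0("bb_", code), "bb_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Evaluate code with a temporary RNG seed, restoring global RNG state
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# ISO-8601 UTC timestamp; `when` defaults to now.
iso_time <- function(when = Sys.time()) {
  format(as.POSIXct(when, tz = "UTC"), "%Y-%m-%dT%H:%M:%SZ")
}

is_iso_date <- function(x) {
  grepl("^\\d{4}-\\d{2}-\\d{2}", x) &
    !is.na(suppressWarnings(as.Date(substr(x, 1, 10), format = "%Y-%m-%d")))
}

# Zero-row data.frame constructor from name = class pairs.
empty_df <- function(...) {
  cols <- list(...)
  out <- lapply(cols, function(cl) vector(cl, 0L))
  as.data.frame(out, stringsAsFactors = FALSE)
}

df_append <- function(df, row) {
  # row: named list covering df's columns
  rbind(df, as.data.frame(row, stringsAsFactors = FALSE))
}

assert_scalar_chr <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
    bb_stop("bad_argument", "%s must be a single non-empty string", what)
  invisible(x)
}
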