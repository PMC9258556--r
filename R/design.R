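# Statistical field-design generation. Six design types are constructed
# natively: alpha lattice (cyclic generating array), square lattice (alpha
# with v = k^2), augmented (RCB of checks with unreplicated tests
# appended), split plot, partially replicated (p-rep) and Westcott
# (unreplicated grid with two systematic checks).

DESIGN_TYPES <- c("alpha", "lattice", "augmented", "splitplot", "prep", "westcott")

new_layout <- function(plot_number, accession, block_number, rep_number,
                       is_check, treatment = NA_character_, row = NA_integer_,
                       col = NA_integer_, design_type) {
  out <- data.frame(
    plot_number = as.integer(plot_number), accession = accession,
    block_number = as.integer(block_number), rep_number = as.integer(rep_number),
    is_check = is_check, treatment = treatment,
    row = as.integer(row), col = as.integer(col), stringsAsFactors = FALSE)
  attr(out, "design_type") <- design_type
  class(out) <- c("bb_layout", "data.frame")
  out
}

#' Generate a randomized field layout
#'
#' Deterministic given `seed`. Per-type parameter rules and structural
#' contracts:
#' \describe{
#'   \item{alpha}{resolvable incomplete-block design: `block_size` k must
#'     divide the number of entries v, `n_reps` r >= 2. Each replicate is
#'     partitioned into v/k blocks of k; every entry appears once per
#'     replicate. Built from a cyclic generating array, then entry labels,
#'     block order and within-block order are randomized.}
#'   \item{lattice}{square lattice: the alpha special case v = k^2.}
#'   \item{augmented}{`checks` non-empty and `n_blocks` b given; each check
#'     appears exactly once in every block, each unreplicated test entry
#'     exactly once overall, tests split as evenly as possible across
#'     blocks, order shuffled within block.}
#'   \item{splitplot}{`whole_plot_factor` treatments randomized within each
#'     of `n_reps` replicate blocks; entries randomized within each whole
#'     plot. The treatment is recorded in the `treatment` column.}
#'   \item{prep}{partially replicated: `replicated_fraction` p in (0, 1];
#'     ceiling(p v) randomly chosen entries appear twice (their two plots in
#'     different blocks when more than one block), the rest once, across
#'     `n_blocks` blocks (default 2).}
#'   \item{westcott}{exactly 2 `checks`; unreplicated entries on a
#'     row-by-column grid with check columns every `check_interval`-th
#'     column (columns 1, 1+ci, 1+2ci, ...), the two checks alternating by
#'     row (check 1 on odd rows, check 2 on even rows). Row/col are
#'     assigned by the construction itself.}
#' }
#'
#' @param design_type one of `alpha`, `lattice`, `augmented`, `splitplot`,
#'   `prep`, `westcott`
#' @param entries character vector of (test) entry accession names, unique
#' @param checks character vector of check accession names (augmented,
#'   westcott)
#' @param n_reps replicates (alpha/lattice/splitplot)
#' @param block_size incomplete-block size k (alpha/lattice)
#' @param n_blocks number of blocks (augmented, prep)
#' @param replicated_fraction p-rep fraction of entries replicated twice
#' @param whole_plot_factor character vector of whole-plot treatments
#'   (splitplot)
#' @param check_interval Westcott check-column spacing (default 3)
#' @param seed integer randomization seed
#' @return a `bb_layout` data.frame with columns `plot_number`,
#'   `accession`, `block_number`, `rep_number`, `is_check`, `treatment`,
#'   `row`, `col`
#' @export
generate_design <- function(design_type, entries, checks = NULL, n_reps = 2L,
                            block_size = NULL, n_blocks = NULL,
                            replicated_fraction = NULL,
                            whole_plot_factor = NULL, check_interval = 3L,
                            seed = 1L) {
  if (!design_type %in% DESIGN_TYPES)
    bb_stop("unknown_design", "unknown design type '%s'", design_type)
  entries <- as.character(entries)
  if (length(entries) == 0) bb_stop("bad_design", "entries must be non-empty")
  if (anyDuplicated(entries)) bb_stop("bad_design", "entries must be unique")
  if (length(intersect(entries, checks)))
    bb_stop("bad_design", "checks must be disjoint from entries")
  with_seed(seed, switch(design_type,
    alpha     = design_alpha(entries, block_size, n_reps),
    lattice   = design_lattice(entries, n_reps),
    augmented = design_augmented(entries, checks, n_blocks),
    splitplot = design_splitplot(entries, whole_plot_factor, n_reps),
    prep      = design_prep(entries, replicated_fraction, n_blocks),
    westcott  = design_westcott(entries, checks, check_interval)))
}

design_alpha <- function(entries, block_size, n_reps, type = "alpha") {
  v <- length(entries)
  if (is.null(block_size)) bb_stop("bad_design", "alpha design needs block_size")
  k <- as.integer(block_size)
  if (k < 2 || v %% k != 0)
    bb_stop("bad_design", "block_size %d must be >= 2 and divide %d entries", k, v)
  if (n_reps < 2) bb_stop("bad_design", "alpha design needs n_reps >= 2")
  s <- v %/% k  # blocks per replicate
  ent <- sample(entries)  # randomize entry labels over the array
  rows <- list()
  plot <- 0L
  for (rep in seq_len(n_reps)) {
    # cyclic generating array: entry (i, j), i in 0..k-1, j in 0..s-1,
    # falls in block (j - i*(rep-1)) mod s of this replicate
    blk_of <- integer(v)
    for (e in seq_len(v)) {
      i <- (e - 1L) %/% s
      j <- (e - 1L) %% s
      blk_of[e] <- ((j - i * (rep - 1L)) %% s) + 1L
    }
    for (b in sample(seq_len(s))) {
      members <- sample(which(blk_of == b))
      for (e in members) {
        plot <- plot + 1L
        rows[[plot]] <- list(plot_number = plot, accession = ent[e],
                             block_number = b, rep_number = rep, is_check = FALSE)
      }
    }
  }
  df <- do.call(rbind, lapply(rows, as.data.frame, stringsAsFactors = FALSE))
  new_layout(df$plot_number, df$accession, df$block_number, df$rep_number,
             df$is_check, design_type = type)
}

design_lattice <- function(entries, n_reps) {
  v <- length(entries)
  k <- as.integer(round(sqrt(v)))
  if (k * k != v)
    bb_stop("bad_design", "lattice needs a square number of entries (got %d)", v)
  design_alpha(entries, k, n_reps, type = "lattice")
}

design_augmented <- function(entries, checks, n_blocks) {
  if (length(checks) == 0) bb_stop("bad_design", "augmented design needs checks")
  if (is.null(n_blocks) || n_blocks < 1)
    bb_stop("bad_design", "augmented design needs n_blocks")
  b <- as.integer(n_blocks)
  groups <- split(sample(entries), rep_len(seq_len(b), length(entries)))
  plot <- 0L; rows <- list()
  for (blk in seq_len(b)) {
    members <- sample(c(checks, groups[[as.character(blk)]] %||% character(0)))
    for (a in members) {
      plot <- plot + 1L
      rows[[plot]] <- list(plot_number = plot, accession = a,
                           block_number = blk, rep_number = 1L,
                           is_check = a %in% checks)
    }
  }
  df <- do.call(rbind, lapply(rows, as.data.frame, stringsAsFactors = FALSE))
  new_layout(df$plot_number, df$accession, df$block_number, df$rep_number,
             df$is_check, design_type = "augmented")
}

design_splitplot <- function(entries, whole_plot_factor, n_reps) {
  if (length(whole_plot_factor) == 0)
    bb_stop("bad_design", "splitplot design needs whole_plot_factor")
  if (n_reps < 1) bb_stop("bad_design", "splitplot needs n_reps >= 1")
  plot <- 0L; rows <- list()
  for (rep in seq_len(n_reps)) {
    for (trt in sample(as.character(whole_plot_factor))) {
      for (a in sample(entries)) {
        plot <- plot + 1L
        rows[[plot]] <- list(plot_number = plot, accession = a,
                             block_number = rep, rep_number = rep,
                             is_check = FALSE, treatment = trt)
      }
    }
  }
  df <- do.call(rbind, lapply(rows, as.data.frame, stringsAsFactors = FALSE))
  new_layout(df$plot_number, df$accession, df$block_number, df$rep_number,
             df$is_check, treatment = df$treatment, design_type = "splitplot")
}

design_prep <- function(entries, replicated_fraction, n_blocks) {
  p <- replicated_fraction
  if (is.null(p) || is.na(p) || p <= 0 || p > 1)
    bb_stop("bad_design", "prep needs replicated_fraction in (0, 1]")
  v <- length(entries)
  b <- as.integer(n_blocks %||% 2L)
  if (b < 1) bb_stop("bad_design", "n_blocks must be >= 1")
  n2 <- as.integer(ceiling(p * v))
  twice <- sample(entries, n2)
  plots <- data.frame(accession = c(entries, twice),
                      rep_number = c(rep(1L, v), rep(2L, n2)),
                      stringsAsFactors = FALSE)
  # spread plots over blocks; put second copies in a different block than
  # the first when there is more than one block
  blk <- integer(nrow(plots))
  first <- sample(rep_len(seq_len(b), v))
  blk[seq_len(v)] <- first
  if (n2 > 0) {
    fb <- first[match(twice, entries)]
    blk[v + seq_len(n2)] <- if (b > 1) ((fb + sample(seq_len(b - 1L), n2, replace = TRUE) - 1L) %% b) + 1L
                            else 1L
  }
  ord <- order(blk, sample(nrow(plots)))
  plots <- plots[ord, ]; blk <- blk[ord]
  new_layout(seq_len(nrow(plots)), plots$accession, blk, plots$rep_number,
             rep(FALSE, nrow(plots)), design_type = "prep")
}

design_westcott <- function(entries, checks, check_interval) {
  if (length(checks) != 2)
    bb_stop("bad_design", "westcott design needs exactly 2 checks")
  ci <- as.integer(check_interval)
  if (ci < 2) bb_stop("bad_design", "check_interval must be >= 2")
  v <- length(entries)
  n_entry_cols <- max(1L, as.integer(ceiling(sqrt(v))))
  # total columns so that non-check columns number n_entry_cols; check
  # columns are 1, 1+ci, 1+2ci, ...
  total_cols <- 0L; ec <- 0L
  while (ec < n_entry_cols) {
    total_cols <- total_cols + 1L
    if ((total_cols - 1L) %% ci != 0L) ec <- ec + 1L
  }
  is_check_col <- ((seq_len(total_cols) - 1L) %% ci) == 0L
  n_rows <- as.integer(ceiling(v / n_entry_cols))
  ent <- sample(entries)
  plot <- 0L; e <- 0L; rows <- list()
  for (r in seq_len(n_rows)) {
    if (e >= v) break
    for (cc in seq_len(total_cols)) {
      if (is_check_col[cc]) {
        a <- checks[((r - 1L) %% 2L) + 1L]; chk <- TRUE
      } else {
        if (e >= v) next
        e <- e + 1L; a <- ent[e]; chk <- FALSE
      }
      plot <- plot + 1L
      rows[[plot]] <- list(plot_number = plot, accession = a,
                           block_number = 1L, rep_number = 1L,
                           is_check = chk, row = r, col = cc)
    }
  }
  df <- do.call(rbind, lapply(rows, as.data.frame, stringsAsFactors = FALSE))
  new_layout(df$plot_number, df$accession, df$block_number, df$rep_number,
             df$is_check, row = df$row, col = df$col, design_type = "westcott")
}

#' Fill field row/column coordinates over a layout
#'
#' Walks plots in `plot_number` order over a grid `n_cols` wide.
#' `serpentine` fills row 1 left to right, row 2 right to left, and so on;
#' `zigzag` fills every row left to right. The mapping plot -> (row, col)
#' is a bijection.
#'
#' @param layout a `bb_layout`
#' @param n_cols grid width (>= 1)
#' @param order `"serpentine"` or `"zigzag"`
#' @return the layout with `row` and `col` filled
#' @export
assign_coordinates <- function(layout, n_cols, order = c("serpentine", "zigzag")) {
  order <- match.arg(order)
  n_cols <- as.integer(n_cols)
  if (n_cols < 1) bb_stop("bad_design", "n_cols must be >= 1")
  idx <- order(layout$plot_number)
  pos <- seq_along(idx) - 1L
  r <- pos %/% n_cols + 1L
  c0 <- pos %% n_cols + 1L
  if (order == "serpentine") c0 <- ifelse(r %% 2L == 0L, n_cols + 1L - c0, c0)
  layout$row[idx] <- r
  layout$col[idx] <- c0
  layout
}

#' Structural checker for generated layouts
#'
#' Verifies the design contracts stated in [generate_design()]: entry
#' conservation (the accession multiset equals what the parameters imply),
#' per-replicate occurrence, block sizes and check placement. Used by the
#' test-suite over many seeds, and exported so users can audit uploaded
#' layouts.
#'
#' @inheritParams generate_design
#' @param layout a `bb_layout` to check
#' @return `TRUE` if all contracts hold, otherwise a character vector of
#'   problems
#' @export
check_design <- function(layout, design_type, entries, checks = NULL,
                         n_reps = 2L, block_size = NULL, n_blocks = NULL,
                         replicated_fraction = NULL, whole_plot_factor = NULL,
                         check_interval = 3L) {
  p <- character(0)
  add <- function(msg) p <<- c(p, msg)
  if (!identical(sort(unique(layout$plot_number)), seq_len(nrow(layout))))
    add("plot numbers are not 1..n")
  tab0 <- table(layout$accession)
  tab <- function(a) {
    x <- as.integer(tab0[a]); x[is.na(x)] <- 0L; stats::setNames(x, a)
  }
  v <- length(entries)
  if (design_type %in% c("alpha", "lattice")) {
    k <- if (design_type == "lattice") as.integer(round(sqrt(v))) else as.integer(block_size)
    if (!all(tab(entries) == n_reps)) add("entries do not each appear n_reps times")
    if (length(setdiff(names(tab0), entries))) add("foreign accessions present")
    for (rep in unique(layout$rep_number)) {
      lr <- layout[layout$rep_number == rep, ]
      if (!setequal(lr$accession, entries) || nrow(lr) != v)
        add(sprintf("replicate %d is not a complete replicate", rep))
      bs <- table(lr$block_number)
      if (!all(bs == k)) add(sprintf("replicate %d has blocks of size != %d", rep, k))
      if (length(bs) != v %/% k) add(sprintf("replicate %d block count wrong", rep))
    }
  } else if (design_type == "augmented") {
    b <- as.integer(n_blocks)
    if (!all(tab(entries) == 1L)) add("test entries must appear exactly once")
    if (!all(tab(checks) == b)) add("each check must appear once per block")
    for (blk in seq_len(b)) {
      lb <- layout[layout$block_number == blk, ]
      if (!all(vapply(checks, function(ch) sum(lb$accession == ch) == 1L, logical(1))))
        add(sprintf("block %d does not contain each check exactly once", blk))
    }
    if (!identical(sort(unique(layout$block_number)), seq_len(b))) add("block numbering wrong")
    if (!all(layout$is_check == (layout$accession %in% checks))) add("is_check flags wrong")
  } else if (design_type == "splitplot") {
    w <- length(whole_plot_factor)
    if (nrow(layout) != n_reps * w * v) add("plot count != reps * treatments * entries")
    for (rep in seq_len(n_reps)) for (trt in whole_plot_factor) {
      wp <- layout[layout$rep_number == rep & layout$treatment == trt, ]
      if (!setequal(wp$accession, entries) || nrow(wp) != v)
        add(sprintf("whole plot (rep %d, %s) is not a complete entry set", rep, trt))
    }
  } else if (design_type == "prep") {
    n2 <- as.integer(ceiling(replicated_fraction * v))
    cnt <- tab(entries)
    if (sum(cnt == 2L) != n2) add("number of twice-replicated entries wrong")
    if (sum(cnt == 1L) != v - n2) add("number of once-replicated entries wrong")
    if (nrow(layout) != v + n2) add("plot count wrong")
    if (any(!names(tab0) %in% entries)) add("foreign accessions present")
  } else if (design_type == "westcott") {
    if (!all(tab(entries) == 1L)) add("entries must be unreplicated")
    ci <- as.integer(check_interval)
    chk <- layout[layout$is_check, ]
    ent <- layout[!layout$is_check, ]
    if (!setequal(ent$accession, entries)) add("entry set wrong")
    if (any((chk$col - 1L) %% ci != 0L)) add("checks off the systematic columns")
    if (any((ent$col - 1L) %% ci == 0L)) add("entries on check columns")
    exp_chk <- checks[((chk$row - 1L) %% 2L) + 1L]
    if (!all(chk$accession == exp_chk)) add("checks do not alternate by row")
    if (anyDuplicated(layout[, c("row", "col")])) add("duplicate grid cells")
  } else {
    add(sprintf("unknown design type '%s'", design_type))
  }
  if (length(p)) p else TRUE
}
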