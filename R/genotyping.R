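# Genotyping: plates, protocols, VCF-backed dosage storage, dosage
# matrices, the genomic relationship matrix, and VCF / TSV export.

PLATE_FORMATS <- list(`96` = list(rows = LETTERS[1:8], cols = 12L),
                      `384` = list(rows = LETTERS[1:16], cols = 24L))

#' Create a PCR plate with row-major sample assignment
#'
#' Samples are assigned to wells row-major (A01, A02, ...); well ids use
#' zero-padded two-digit columns. Format 96 is 8 x 12 (rows A-H), format
#' 384 is 16 x 24 (rows A-P).
#'
#' @param store a store
#' @param name unique plate name
#' @param format 96 or 384
#' @param samples ordered character vector of sample names (no duplicates,
#'   at most the plate capacity)
#' @return the plate (list with `name`, `format`, `wells`)
#' @export
create_plate <- function(store, name, format, samples) {
  check_store(store)
  assert_scalar_chr(name, "plate name")
  fmt <- PLATE_FORMATS[[as.character(format)]]
  if (is.null(fmt)) bb_stop("bad_format", "plate format must be 96 or 384")
  if (name %in% names(store$plates)) bb_stop("duplicate_name", "plate '%s' exists", name)
  capacity <- length(fmt$rows) * fmt$cols
  samples <- as.character(samples)
  if (length(samples) > capacity)
    bb_stop("capacity_exceeded", "%d samples exceed %d-well capacity",
            length(samples), capacity)
  if (anyDuplicated(samples))
    bb_stop("duplicate_sample", "duplicate sample within one plate")
  well_ids <- as.vector(t(outer(fmt$rows, seq_len(fmt$cols),
                                function(r, c) sprintf("%s%02d", r, c))))
  plate <- list(name = name, format = as.integer(format),
                wells = stats::setNames(samples, well_ids[seq_along(samples)]))
  store$plates[[name]] <- plate
  plate
}

# Resolve a sample name to a store entity (accession via name/synonym, or
# observation unit). Returns the resolved name or NA.
resolve_sample <- function(store, sample) {
  if (sample %in% store$units$name) return(sample)
  acc <- tryCatch(find_accession(store, sample), bb_empty_name = function(e) NULL)
  if (!is.null(acc)) return(acc$name)
  NA_character_
}

#' Store per-sample marker dosages under a genotyping protocol
#'
#' The programmatic ingestion route shared by [load_vcf()] and the
#' simulator. Creates the protocol if needed (markers sorted by chromosome
#' and position); when the protocol exists, marker names must be a subset
#' of its markers. Dosages are ALT-allele counts in `0..ploidy`, `NA` for
#' missing. Samples must resolve to an accession or observation unit;
#' unresolved samples are reported, not stored.
#'
#' @param store a store
#' @param protocol_name protocol name
#' @param scores named list: sample name -> named numeric vector of
#'   marker dosages, or a samples x markers matrix with dimnames
#' @param markers data.frame `name,chrom,pos,ref_allele,alt_allele`
#'   (required when the protocol does not exist yet)
#' @param reference_genome,project,metadata protocol metadata
#' @param ploidy protocol ploidy (default 2)
#' @return report list: `samples_stored`, `unmatched`
#' @export
add_genotypes <- function(store, protocol_name, scores, markers = NULL,
                          reference_genome = "unknown", project = NA_character_,
                          metadata = list(), ploidy = 2L) {
  check_store(store)
  if (is.matrix(scores))
    scores <- stats::setNames(
      lapply(seq_len(nrow(scores)),
             function(i) stats::setNames(as.numeric(scores[i, ]), colnames(scores))),
      rownames(scores))
  proto <- store$protocols[[protocol_name]]
  if (is.null(proto)) {
    if (is.null(markers)) bb_stop("unknown_protocol",
                                  "protocol '%s' does not exist and no markers given", protocol_name)
    if (anyDuplicated(markers$name))
      bb_stop("duplicate_marker", "marker names must be unique within a protocol")
    markers <- markers[order(markers$chrom, markers$pos), , drop = FALSE]
    rownames(markers) <- NULL
    proto <- list(name = protocol_name, project = project,
                  reference_genome = reference_genome, ploidy = as.integer(ploidy),
                  markers = markers, metadata = metadata)
    store$protocols[[protocol_name]] <- proto
    store$genotypes[[protocol_name]] <- list()
  }
  stored <- character(0); unmatched <- character(0)
  for (sm in names(scores)) {
    res <- resolve_sample(store, sm)
    if (is.na(res)) { unmatched <- c(unmatched, sm); next }
    v <- scores[[sm]]
    bad <- setdiff(names(v), proto$markers$name)
    if (length(bad)) bb_stop("unknown_marker", "sample '%s' scores unknown markers (%s...)",
                             sm, bad[1])
    if (any(v < 0 | v > proto$ploidy, na.rm = TRUE))
      bb_stop("bad_dosage", "dosage out of 0..%d for sample '%s'", proto$ploidy, sm)
    store$genotypes[[protocol_name]][[res]] <- v
    stored <- c(stored, res)
  }
  list(samples_stored = stored, unmatched = unmatched)
}

#' Load genotypes from a VCF file into a protocol
#'
#' Reads GT across arbitrary ploidy: the dosage is the count of ALT alleles
#' (diploid 0/1 -> 1, 1/1 -> 2; triploid 0/1/1 -> 2); any missing allele
#' (`.`) makes the score missing. Only biallelic SNP records are stored;
#' multi-allelic or non-SNP records are skipped and counted. Sample columns
#' can be renamed to store names via `sample_map`; samples that resolve to
#' no accession or unit are reported under `unmatched`.
#'
#' @param store a store
#' @param path VCF file (v4.x, GT subfield; other FORMAT fields ignored)
#' @param protocol_name protocol to create or extend
#' @param sample_map optional named character vector, VCF column name ->
#'   store sample name
#' @param reference_genome,project,metadata,ploidy protocol metadata when
#'   the protocol is created
#' @return report list: `markers_added`, `samples_stored`,
#'   `records_skipped`, `unmatched`
#' @export
load_vcf <- function(store, path, protocol_name, sample_map = NULL,
                     reference_genome = "unknown", project = NA_character_,
                     metadata = list(), ploidy = 2L) {
  check_store(store)
  if (!file.exists(path)) bb_stop("bad_file", "no such file '%s'", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n_rec <- nrow(fix)
  if (n_rec == 0) bb_stop("empty_vcf", "no usable records in '%s'", path)
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  usable <- !is.na(alt) & !grepl(",", alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  skipped <- sum(!usable)
  if (!any(usable)) bb_stop("empty_vcf", "zero usable biallelic SNP records in '%s'", path)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(ids) | ids == "."]
  markers <- data.frame(name = ids[usable], chrom = fix[usable, "CHROM"],
                        pos = as.integer(fix[usable, "POS"]),
                        ref_allele = ref[usable], alt_allele = alt[usable],
                        stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) bb_stop("bad_file", "VCF has no GT field")
  gt <- gt[usable, , drop = FALSE]
  vcf_samples <- colnames(gt)
  dosage_of <- function(g) {
    if (is.na(g)) return(NA_real_)
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".")) return(NA_real_)
    sum(al == "1")
  }
  scores <- list()
  for (j in seq_along(vcf_samples)) {
    nm <- vcf_samples[j]
    if (!is.null(sample_map) && nm %in% names(sample_map)) nm <- sample_map[[nm]]
    scores[[nm]] <- stats::setNames(vapply(gt[, j], dosage_of, numeric(1),
                                           USE.NAMES = FALSE), markers$name)
  }
  rep <- add_genotypes(store, protocol_name, scores, markers = markers,
                       reference_genome = reference_genome, project = project,
                       metadata = metadata, ploidy = ploidy)
  list(markers_added = nrow(markers), samples_stored = rep$samples_stored,
       records_skipped = skipped, unmatched = rep$unmatched)
}

#' Dosage matrix and allele frequencies for a protocol
#'
#' Assembles the samples x markers dosage matrix in protocol marker order.
#' The ALT allele frequency of marker j is `mean(dosage)/ploidy` over
#' non-missing entries. `impute = "mean"` replaces missing entries with the
#' column mean dosage (markers missing in every sample are dropped and
#' reported); `impute = "none"` leaves `NA`s. Monomorphic markers (p = 0 or
#' 1) are reported.
#'
#' @param store a store
#' @param protocol protocol name
#' @param samples sample names (default: all genotyped samples)
#' @param impute `"none"` or `"mean"`
#' @return list with `X` (matrix), `p` (named frequency vector),
#'   `monomorphic` (marker names), `dropped` (all-missing markers removed
#'   under mean imputation), `ploidy`
#' @export
dosage_matrix <- function(store, protocol, samples = NULL,
                          impute = c("none", "mean")) {
  check_store(store)
  impute <- match.arg(impute)
  proto <- store$protocols[[protocol]]
  if (is.null(proto)) bb_stop("unknown_protocol", "no protocol '%s'", protocol)
  geno <- store$genotypes[[protocol]]
  samples <- samples %||% names(geno)
  missing_s <- setdiff(samples, names(geno))
  if (length(missing_s))
    bb_stop("unknown_sample", "no genotypes for sample '%s' under '%s'",
            missing_s[1], protocol)
  if (length(samples) == 0) bb_stop("empty_protocol", "no samples under '%s'", protocol)
  mk <- proto$markers$name
  X <- matrix(NA_real_, length(samples), length(mk),
              dimnames = list(samples, mk))
  for (s in samples) X[s, names(geno[[s]])] <- geno[[s]]
  nm_mean <- colMeans(X, na.rm = TRUE)  # NaN for all-missing columns
  dropped <- character(0)
  if (impute == "mean") {
    all_missing <- !is.finite(nm_mean)
    if (any(all_missing)) {
      dropped <- mk[all_missing]
      X <- X[, !all_missing, drop = FALSE]
      nm_mean <- nm_mean[!all_missing]
      mk <- mk[!all_missing]
    }
    for (j in which(colSums(is.na(X)) > 0))
      X[is.na(X[, j]), j] <- nm_mean[j]
  }
  p <- nm_mean / proto$ploidy
  mono <- mk[is.finite(p) & (p == 0 | p == 1)]
  list(X = X, p = p, monomorphic = mono, dropped = dropped,
       ploidy = proto$ploidy)
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' With dosage matrix X (samples x markers) and observed ALT allele
#' frequencies p, columns are centered at 2p (Z = X - 2p) and
#' `G = Z Z' / (2 sum_j p_j (1 - p_j))`. Monomorphic markers contribute
#' nothing and are excluded from both Z and the denominator. The matrix
#' must be complete (use `impute = "mean"` in [dosage_matrix()] first).
#'
#' @param X complete samples x markers dosage matrix
#' @param p named ALT allele frequency vector (one per column of X)
#' @param ploidy only diploid (2) is supported
#' @return symmetric samples x samples matrix
#' @export
compute_grm <- function(X, p, ploidy = 2L) {
  if (ploidy != 2L)
    bb_stop("bad_ploidy", "GRM supports diploid dosages only; export dosages instead")
  if (any(is.na(X))) bb_stop("missing_values", "dosage matrix must be complete (impute first)")
  if (length(p) != ncol(X)) bb_stop("bad_argument", "one frequency per marker required")
  poly <- is.finite(p) & p > 0 & p < 1
  if (!any(poly)) bb_stop("no_polymorphic_markers", "zero polymorphic markers")
  Xp <- X[, poly, drop = FALSE]
  pp <- p[poly]
  Z <- sweep(Xp, 2, 2 * pp)
  denom <- 2 * sum(pp * (1 - pp))
  G <- tcrossprod(Z) / denom
  (G + t(G)) / 2
}

#' Convenience wrapper: GRM for a protocol's samples
#' @inheritParams dosage_matrix
#' @return symmetric matrix
#' @export
grm <- function(store, protocol, samples = NULL) {
  dm <- dosage_matrix(store, protocol, samples, impute = "mean")
  compute_grm(dm$X, dm$p, ploidy = dm$ploidy)
}

#' Export stored genotypes as a VCF 4.2 file
#'
#' One record per protocol marker (protocol order, i.e. sorted by
#' chromosome and position), GT reconstructed from dosage assuming unphased
#' diploid: 0 -> `0/0`, 1 -> `0/1`, 2 -> `1/1`, missing -> `./.`.
#' Re-loading the file reproduces the dosages exactly. Refused for ploidy
#' above 2 (use [export_dosage_tsv()]).
#'
#' @param store a store
#' @param protocol protocol name
#' @param samples sample names (default all)
#' @param path output path
#' @return the path (invisibly)
#' @export
export_vcf <- function(store, protocol, path, samples = NULL) {
  check_store(store)
  proto <- store$protocols[[protocol]]
  if (is.null(proto)) bb_stop("unknown_protocol", "no protocol '%s'", protocol)
  if (proto$ploidy > 2L)
    bb_stop("bad_ploidy",
            "VCF export assumes diploid GT; use export_dosage_tsv() for ploidy %d",
            proto$ploidy)
  dm <- dosage_matrix(store, protocol, samples, impute = "none")
  X <- dm$X
  gt_of <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  header <- c("##fileformat=VCFv4.2",
              sprintf("##source=breedbox;protocol=%s", protocol),
              sprintf("##reference=%s", proto$reference_genome),
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(X)), collapse = "\t"))
  mk <- proto$markers
  body <- vapply(seq_len(nrow(mk)), function(j) {
    d <- X[, mk$name[j]]
    gts <- ifelse(is.na(d), "./.", gt_of[as.character(d)])
    paste(c(mk$chrom[j], mk$pos[j], mk$name[j], mk$ref_allele[j],
            mk$alt_allele[j], ".", "PASS", ".", "GT", gts), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Export dosages as a TSV (samples x markers, NA for missing)
#' @inheritParams export_vcf
#' @export
export_dosage_tsv <- function(store, protocol, path, samples = NULL) {
  dm <- dosage_matrix(store, protocol, samples, impute = "none")
  df <- data.frame(sample = rownames(dm$X), dm$X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}
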