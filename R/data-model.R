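#' @import Matrix
#' @importFrom methods as is new
#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats setNames
NULL

# ---- annotated count matrix -------------------------------------------------

#' Annotated single-nucleus count matrix
#'
#' Container for a genes-by-cells non-negative integer UMI (or fragment-derived
#' gene activity) count matrix with per-cell metadata. Counts are stored as a
#' sparse `dgCMatrix` so zero-dominant matrices never require dense memory.
#'
#' @param counts genes-by-cells matrix of non-negative integers (dense or
#'   sparse; coerced to `dgCMatrix`). Dimnames, when present, must agree with
#'   `gene_ids` / `cell_ids`.
#' @param gene_ids character vector of unique gene identifiers (rows).
#' @param cell_ids character vector of unique cell barcodes (columns).
#' @param cell_meta tibble keyed by cell with at least a `sample_id` column;
#'   optional columns `cell_type`, `cluster_id`, `group_label`. Missing
#'   optional columns are filled with `NA`.
#'
#' @return An object of class `sn_counts`: a list with elements `counts`,
#'   `gene_ids`, `cell_ids`, `cell_meta`.
#' @export
sn_counts <- function(counts, gene_ids = rownames(counts),
                      cell_ids = colnames(counts), cell_meta) {
  counts <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (nrow(counts) != length(gene_ids) || ncol(counts) != length(cell_ids)) {
    abort("counts dimensions do not match gene/cell id lists", class = "nephromics_format_error")
  }
  if (anyDuplicated(gene_ids)) abort("duplicate gene ids", class = "nephromics_format_error")
  if (anyDuplicated(cell_ids)) abort("duplicate cell ids", class = "nephromics_format_error")
  if (length(counts@x) && min(counts@x) < 0) {
    abort("negative counts", class = "nephromics_format_error")
  }
  cell_meta <- as_tibble(cell_meta)
  if (!"sample_id" %in% names(cell_meta) || anyNA(cell_meta$sample_id)) {
    abort("every cell needs a sample_id", class = "nephromics_format_error")
  }
  if (nrow(cell_meta) != length(cell_ids)) {
    abort("cell_meta rows do not match cells", class = "nephromics_format_error")
  }
  for (col in c("cell_type", "cluster_id", "group_label")) {
    if (!col %in% names(cell_meta)) cell_meta[[col]] <- NA_character_
  }
  dimnames(counts) <- list(gene_ids, cell_ids)
  structure(
    list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
         cell_meta = cell_meta),
    class = "sn_counts"
  )
}

#' @export
print.sn_counts <- function(x, ...) {
  cat(sprintf("<sn_counts> %d genes x %d cells, %d samples\n",
              length(x$gene_ids), length(x$cell_ids),
              length(unique(x$cell_meta$sample_id))))
  tt <- table(x$cell_meta$cell_type, useNA = "ifany")
  cat("  cell types:", paste(sprintf("%s=%d", names(tt), tt), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.sn_counts <- function(x) dim(x$counts)

#' Subset an annotated count matrix by cells (and optionally genes)
#'
#' @param x an `sn_counts` or `norm_matrix` object.
#' @param cells logical/integer/character index of cells to keep.
#' @param genes optional index of genes to keep.
#' @return object of the same class.
#' @export
subset_cells <- function(x, cells, genes = NULL) {
  stopifnot(inherits(x, c("sn_counts", "norm_matrix")))
  slot <- if (inherits(x, "sn_counts")) "counts" else "values"
  m <- x[[slot]]
  if (is.character(cells)) cells <- match(cells, x$cell_ids)
  keep_g <- if (is.null(genes)) seq_along(x$gene_ids) else genes
  m <- m[keep_g, cells, drop = FALSE]
  out <- x
  out[[slot]] <- m
  out$gene_ids <- x$gene_ids[keep_g]
  out$cell_ids <- colnames(m)
  out$cell_meta <- x$cell_meta[cells, , drop = FALSE]
  out
}

# ---- normalized matrix ------------------------------------------------------

#' Depth-normalized log expression matrix
#'
#' Same shape contract as the source counts; values are zero exactly where
#' counts are zero (log1p of a scaled count). Constructed by [lognormalize()].
#'
#' @param values sparse genes-by-cells matrix of non-negative reals.
#' @param gene_ids,cell_ids,cell_meta as in [sn_counts()].
#' @param scale_factor positive scale factor used during normalization.
#' @return An object of class `norm_matrix`.
#' @export
norm_matrix <- function(values, gene_ids = rownames(values),
                        cell_ids = colnames(values), cell_meta,
                        scale_factor = 1e4) {
  values <- as(as(values, "CsparseMatrix"), "generalMatrix")
  stopifnot(scale_factor > 0)
  obj <- sn_counts(values, gene_ids, cell_ids, cell_meta)
  obj$values <- obj$counts
  obj$counts <- NULL
  obj$scale_factor <- scale_factor
  class(obj) <- "norm_matrix"
  obj
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat(sprintf("<norm_matrix> %d genes x %d cells (scale factor %g)\n",
              length(x$gene_ids), length(x$cell_ids), x$scale_factor))
  invisible(x)
}

#' @export
dim.norm_matrix <- function(x) dim(x$values)

# ---- gene models ------------------------------------------------------------

#' Validate a gene-model table
#'
#' Gene models use 1-based inclusive coordinates. The transcription start site
#' is the `start` for + strand genes and the `end` for - strand genes; a `tss`
#' column is added if absent.
#'
#' @param genes data frame with columns `gene_id`, `chrom`, `strand`
#'   (`+`/`-`), `start`, `end` and optionally `tss`.
#' @return tibble with a guaranteed `tss` column.
#' @export
gene_model <- function(genes) {
  genes <- as_tibble(genes)
  req <- c("gene_id", "chrom", "strand", "start", "end")
  if (!all(req %in% names(genes))) {
    abort(paste("gene model missing columns:",
                paste(setdiff(req, names(genes)), collapse = ", ")),
          class = "nephromics_format_error")
  }
  if (any(genes$start > genes$end)) {
    abort("gene model rows with start > end", class = "nephromics_format_error")
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    abort("gene strand must be + or -", class = "nephromics_format_error")
  }
  if (!"tss" %in% names(genes)) {
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  }
  if (any(genes$tss < genes$start | genes$tss > genes$end)) {
    abort("tss outside gene body", class = "nephromics_format_error")
  }
  genes
}

# ---- peaks ------------------------------------------------------------------

#' Validate a peak table
#'
#' Peaks are 0-based half-open genomic intervals with a summit position and a
#' non-negative signal score. `peak_id` is added (chrom:start-end) if absent.
#'
#' @param peaks data frame with columns `chrom`, `start`, `end` and optional
#'   `summit` (absolute position; defaults to the interval midpoint) and
#'   `score` (defaults to 0).
#' @param resized if `TRUE`, additionally require every peak to be 501 bp.
#' @return tibble with columns `peak_id`, `chrom`, `start`, `end`, `summit`,
#'   `score`.
#' @export
peak_table <- function(peaks, resized = FALSE) {
  peaks <- as_tibble(peaks)
  req <- c("chrom", "start", "end")
  if (!all(req %in% names(peaks))) {
    abort("peak table needs chrom/start/end", class = "nephromics_format_error")
  }
  if (any(peaks$start >= peaks$end)) {
    abort("peak with start >= end", class = "nephromics_format_error")
  }
  if (!"score" %in% names(peaks)) peaks$score <- 0
  if (!"summit" %in% names(peaks)) {
    peaks$summit <- peaks$start + floor((peaks$end - peaks$start) / 2)
  }
  if (any(peaks$summit < peaks$start | peaks$summit >= peaks$end)) {
    abort("summit outside [start, end)", class = "nephromics_format_error")
  }
  if (any(peaks$score < 0)) abort("negative peak score", class = "nephromics_format_error")
  if (resized && any(peaks$end - peaks$start != 501)) {
    abort("resized peaks must be 501 bp", class = "nephromics_format_error")
  }
  if (!"peak_id" %in% names(peaks)) {
    peaks$peak_id <- sprintf("%s:%d-%d", peaks$chrom, peaks$start, peaks$end)
  }
  dplyr::relocate(peaks, "peak_id", "chrom", "start", "end", "summit", "score")
}

#' Peaks-by-cells fragment count matrix
#'
#' @param counts peaks-by-cells non-negative integer matrix.
#' @param peaks peak table (see [peak_table()]); one row per count row.
#' @param cell_ids,cell_meta as in [sn_counts()]; `cell_meta` should carry a
#'   `frip` column (fraction of fragments in peaks, in \[0, 1\]).
#' @return An object of class `peak_matrix`.
#' @export
peak_matrix <- function(counts, peaks, cell_ids = colnames(counts), cell_meta) {
  peaks <- peak_table(peaks)
  counts <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  if (nrow(counts) != nrow(peaks)) {
    abort("peak count rows do not match peak table", class = "nephromics_format_error")
  }
  obj <- sn_counts(counts, gene_ids = peaks$peak_id, cell_ids = cell_ids,
                   cell_meta = cell_meta)
  if (!"frip" %in% names(obj$cell_meta)) obj$cell_meta$frip <- NA_real_
  fr <- obj$cell_meta$frip
  if (any(!is.na(fr) & (fr < 0 | fr > 1))) {
    abort("frip outside [0, 1]", class = "nephromics_format_error")
  }
  obj$peaks <- peaks
  class(obj) <- c("peak_matrix", "sn_counts")
  obj
}

# ---- bulk cohort ------------------------------------------------------------

#' Bulk expression / protein cohort with clinical metadata
#'
#' @param expr genes-by-samples numeric matrix of log2 FPKM expression.
#' @param clinical tibble with one row per sample: `sample_id`, `tissue`
#'   (`tumor`/`NAT`) and optional `stage` (I-IV), `mutation_group`,
#'   `surv_time` (non-negative), `event` (0/1). Missing clinical fields
#'   propagate as `NA`.
#' @param protein optional genes-by-samples protein abundance matrix (gene
#'   rows need not match `expr`).
#' @return An object of class `bulk_cohort`.
#' @export
bulk_cohort <- function(expr, clinical, protein = NULL) {
  expr <- as.matrix(expr)
  clinical <- as_tibble(clinical)
  if (!all(c("sample_id", "tissue") %in% names(clinical))) {
    abort("clinical table needs sample_id and tissue", class = "nephromics_format_error")
  }
  if (is.null(colnames(expr))) colnames(expr) <- clinical$sample_id
  if (!identical(sort(colnames(expr)), sort(clinical$sample_id))) {
    abort("expression samples do not match clinical table", class = "nephromics_format_error")
  }
  if (!all(clinical$tissue %in% c("tumor", "NAT"))) {
    abort("tissue must be tumor or NAT", class = "nephromics_format_error")
  }
  for (col in c("stage", "mutation_group")) {
    if (!col %in% names(clinical)) clinical[[col]] <- NA_character_
  }
  for (col in c("surv_time", "event")) {
    if (!col %in% names(clinical)) clinical[[col]] <- NA_real_
  }
  st <- clinical$surv_time
  if (any(!is.na(st) & st < 0)) abort("negative survival time", class = "nephromics_format_error")
  if (!is.null(protein)) protein <- as.matrix(protein)
  structure(list(expr = expr, protein = protein, clinical = clinical),
            class = "bulk_cohort")
}

#' @export
print.bulk_cohort <- function(x, ...) {
  cat(sprintf("<bulk_cohort> %d genes x %d samples (%d tumor, %d NAT)%s\n",
              nrow(x$expr), ncol(x$expr), sum(x$clinical$tissue == "tumor"),
              sum(x$clinical$tissue == "NAT"),
              if (is.null(x$protein)) "" else sprintf("; protein for %d genes", nrow(x$protein))))
  invisible(x)
}

# ---- CNV segments -----------------------------------------------------------

#' Validate a copy-number segment table
#'
#' @param segments data frame with columns `sample_id`, `chrom`, `start`,
#'   `end`, `log2cr` and optional `arm`.
#' @return tibble.
#' @export
segment_table <- function(segments) {
  segments <- as_tibble(segments)
  req <- c("sample_id", "chrom", "start", "end", "log2cr")
  if (!all(req %in% names(segments))) {
    abort(paste("segment table missing:", paste(setdiff(req, names(segments)), collapse = ", ")),
          class = "nephromics_format_error")
  }
  if (any(segments$start >= segments$end)) {
    abort("segment with start >= end", class = "nephromics_format_error")
  }
  if (!"arm" %in% names(segments)) segments$arm <- NA_character_
  segments
}

# ---- PWM --------------------------------------------------------------------

#' Position weight matrix (probability form)
#'
#' Counts are normalized column-wise to probabilities; a pseudocount can be
#' applied to avoid zero probabilities before log-odds scoring.
#'
#' @param matrix 4-by-L numeric matrix of counts or probabilities, rows in
#'   A, C, G, T order.
#' @param motif_id motif identifier.
#' @param background length-4 background probabilities (sums to 1).
#' @param pseudocount added to counts before normalization (default 0).
#' @return An object of class `pwm` with elements `motif_id`, `matrix`
#'   (probabilities), `background`.
#' @export
pwm <- function(matrix, motif_id, background = rep(0.25, 4), pseudocount = 0) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != 4 || ncol(matrix) < 1) {
    abort("PWM must be 4 x L with L >= 1", class = "nephromics_format_error")
  }
  if (any(matrix < 0)) abort("negative PWM entries", class = "nephromics_format_error")
  matrix <- matrix + pseudocount
  cs <- colSums(matrix)
  if (any(cs == 0)) abort("PWM column sums to zero", class = "nephromics_format_error")
  prob <- sweep(matrix, 2, cs, "/")
  if (abs(sum(background) - 1) > 1e-9 || length(background) != 4) {
    abort("background must be 4 probabilities summing to 1", class = "nephromics_format_error")
  }
  rownames(prob) <- c("A", "C", "G", "T")
  structure(list(motif_id = motif_id, matrix = prob, background = background),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s, length %d\n", x$motif_id, ncol(x$matrix)))
  invisible(x)
}

# ---- gene sets --------------------------------------------------------------

#' Gene set collection
#'
#' @param sets named list of character vectors; names unique, no empty set.
#' @return named list of class `gene_sets`.
#' @export
gene_sets <- function(sets) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    abort("gene sets need unique names", class = "nephromics_format_error")
  }
  if (any(lengths(sets) == 0)) abort("empty gene set", class = "nephromics_format_error")
  structure(lapply(sets, as.character), class = "gene_sets")
}

# ---- coordinate converters --------------------------------------------------

#' Convert between 0-based half-open and 1-based inclusive intervals
#'
#' `bed_to_one_based()` and `one_based_to_bed()` are inverse bijections on
#' valid intervals: BED `[start, end)` maps to 1-based `[start + 1, end]`.
#'
#' @param start,end interval bounds.
#' @return list with `start` and `end` in the target convention.
#' @export
bed_to_one_based <- function(start, end) list(start = start + 1L, end = end)

#' @rdname bed_to_one_based
#' @export
one_based_to_bed <- function(start, end) list(start = start - 1L, end = end)
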