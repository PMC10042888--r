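#' @importFrom readr read_tsv write_tsv cols col_character
NULL

err_fmt <- function(msg, ...) abort(sprintf(msg, ...), class = "nephromics_format_error")

#' Read an annotated count matrix from Matrix Market files
#'
#' Reads a sparse coordinate `.mtx` file plus row (gene) and column (cell) id
#' files, and an optional per-cell metadata TSV keyed by `cell_id`. Cells not
#' present in the metadata, or metadata columns absent from the file, become
#' `NA` (except `sample_id`, which is required when `meta_path` is given; with
#' no metadata all cells are assigned sample `"S1"`).
#'
#' @param mtx_path Matrix Market coordinate file.
#' @param genes_path,cells_path one-id-per-line TSV files (first column used).
#' @param meta_path optional TSV with a `cell_id` column.
#' @return [sn_counts()] object.
#' @export
read_count_matrix <- function(mtx_path, genes_path, cells_path, meta_path = NULL) {
  m <- Matrix::readMM(mtx_path)
  genes <- read_id_column(genes_path)
  cells <- read_id_column(cells_path)
  if (anyDuplicated(genes)) err_fmt("duplicate gene ids in %s", genes_path)
  if (anyDuplicated(cells)) err_fmt("duplicate cell ids in %s", cells_path)
  if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
    err_fmt("matrix is %d x %d but ids are %d x %d",
            nrow(m), ncol(m), length(genes), length(cells))
  }
  if (is.null(meta_path)) {
    meta <- tibble(cell_id = cells, sample_id = "S1")
  } else {
    meta <- read_tsv(meta_path, show_col_types = FALSE)
    if (!"cell_id" %in% names(meta)) err_fmt("metadata %s lacks cell_id column", meta_path)
    meta <- dplyr::left_join(tibble(cell_id = cells), meta, by = "cell_id")
    if (anyNA(meta$sample_id)) err_fmt("cells missing sample_id in %s", meta_path)
  }
  sn_counts(m, genes, cells, meta[setdiff(names(meta), "cell_id")])
}

read_id_column <- function(path) {
  x <- readLines(path)
  x <- x[nzchar(x)]
  vapply(strsplit(x, "\t", fixed = TRUE), `[[`, character(1), 1L)
}

#' Write an annotated count matrix to Matrix Market files
#'
#' Round-trips bit-exactly with [read_count_matrix()].
#'
#' @param x [sn_counts()] object.
#' @param mtx_path,genes_path,cells_path,meta_path output paths.
#' @return `x`, invisibly.
#' @export
write_count_matrix <- function(x, mtx_path, genes_path, cells_path, meta_path = NULL) {
  Matrix::writeMM(x$counts, mtx_path)
  writeLines(x$gene_ids, genes_path)
  writeLines(x$cell_ids, cells_path)
  if (!is.null(meta_path)) {
    write_tsv(dplyr::bind_cols(tibble(cell_id = x$cell_ids), x$cell_meta), meta_path)
  }
  invisible(x)
}

#' Read peaks from a BED file
#'
#' BED columns: chrom, start, end, then optional score and summit offset
#' (relative to `start`). Coordinates stay 0-based half-open. A missing summit
#' column defaults to the interval midpoint.
#'
#' @param path BED file path.
#' @return peak tibble (see [peak_table()]).
#' @export
read_peaks_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) err_fmt("%s line %d: fewer than 3 BED columns", path, which(nf < 3)[1])
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- as.numeric(vapply(fields, `[[`, character(1), 2L))
  end <- as.numeric(vapply(fields, `[[`, character(1), 3L))
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad)) err_fmt("%s line %d: invalid interval", path, bad[1])
  score <- ifelse(nf >= 4, as.numeric(vapply(fields, function(f) if (length(f) >= 4) f[[4]] else "0", character(1))), 0)
  summit <- ifelse(
    nf >= 5,
    start + as.numeric(vapply(fields, function(f) if (length(f) >= 5) f[[5]] else "0", character(1))),
    start + floor((end - start) / 2)
  )
  peak_table(tibble(chrom = chrom, start = start, end = end,
                    score = score, summit = summit))
}

#' Write peaks to a BED file (score and summit-offset columns included)
#'
#' @param peaks peak tibble.
#' @param path output path.
#' @return `peaks`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  peaks <- peak_table(peaks)
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d", peaks$chrom, as.integer(peaks$start),
                     as.integer(peaks$end), format(peaks$score, trim = TRUE),
                     as.integer(peaks$summit - peaks$start)), path)
  invisible(peaks)
}

#' Read gene sets from a GMT file
#'
#' Each line: set name, description, then member gene ids, tab-separated.
#'
#' @param path GMT file path.
#' @return [gene_sets()] collection.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad)) err_fmt("%s line %d: GMT line needs name, description, genes", path, bad[1])
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  gene_sets(sets)
}

#' Write gene sets to a GMT file
#' @param sets [gene_sets()] collection.
#' @param path output path.
#' @return `sets`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  writeLines(vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1)), path)
  invisible(sets)
}

#' Read position frequency matrices in JASPAR text format
#'
#' Records look like `>MA0001.1 NAME` followed by four rows
#' `A [ 4 19 0 ... ]` (brackets optional). Counts are normalized to column
#' probabilities with the given pseudocount.
#'
#' @param path JASPAR PFM file.
#' @param background background nucleotide probabilities.
#' @param pseudocount added to counts before normalization.
#' @return list of [pwm()] objects named by motif id.
#' @export
read_jaspar_pfm <- function(path, background = rep(0.25, 4), pseudocount = 0.01) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) err_fmt("%s: no JASPAR records found", path)
  ends <- c(starts[-1] - 1L, length(lines))
  out <- list()
  for (i in seq_along(starts)) {
    header <- sub("^>\\s*", "", lines[starts[i]])
    motif_id <- strsplit(header, "\\s+")[[1]][1]
    body <- lines[(starts[i] + 1L):ends[i]]
    if (length(body) != 4) err_fmt("%s motif %s: expected 4 base rows", path, motif_id)
    rows <- lapply(body, function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", trimws(l))
      l <- gsub("[", " ", gsub("]", " ", l, fixed = TRUE), fixed = TRUE)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    if (length(unique(lengths(rows))) != 1) {
      err_fmt("%s motif %s: ragged PFM rows", path, motif_id)
    }
    out[[motif_id]] <- pwm(do.call(rbind, rows), motif_id,
                           background = background, pseudocount = pseudocount)
  }
  out
}

#' Write position frequency matrices in JASPAR text format
#' @param pwms list of [pwm()] objects.
#' @param path output path.
#' @param counts_scale probabilities are written as counts scaled by this total.
#' @return `pwms`, invisibly.
#' @export
write_jaspar_pfm <- function(pwms, path, counts_scale = 100) {
  lines <- unlist(lapply(pwms, function(p) {
    m <- round(p$matrix * counts_scale, 4)
    c(sprintf(">%s %s", p$motif_id, p$motif_id),
      vapply(1:4, function(i) {
        sprintf("%s [ %s ]", c("A", "C", "G", "T")[i],
                paste(format(m[i, ], trim = TRUE), collapse = " "))
      }, character(1)))
  }))
  writeLines(lines, path)
  invisible(pwms)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write sequences to a FASTA file
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `seqs`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(seqs)
}

#' Read a copy-number segment table from TSV
#' @param path TSV with columns sample_id, chrom, start, end, log2cr\[, arm\].
#' @return segment tibble (see [segment_table()]).
#' @export
read_segments <- function(path) {
  segment_table(read_tsv(path, show_col_types = FALSE))
}

#' Write a copy-number segment table to TSV
#' @param segments segment tibble.
#' @param path output path.
#' @return `segments`, invisibly.
#' @export
write_segments <- function(segments, path) {
  write_tsv(segment_table(segments), path)
  invisible(segments)
}

#' Read a bulk cohort from expression / clinical (and optional protein) TSVs
#'
#' The expression and protein tables have a `gene_id` first column and one
#' column per sample; the clinical table has one row per sample.
#'
#' @param expr_path,clinical_path,protein_path TSV paths (`protein_path`
#'   optional).
#' @return [bulk_cohort()] object.
#' @export
read_bulk <- function(expr_path, clinical_path, protein_path = NULL) {
  to_mat <- function(path) {
    d <- read_tsv(path, show_col_types = FALSE)
    if (names(d)[1] != "gene_id") err_fmt("%s: first column must be gene_id", path)
    m <- as.matrix(d[-1])
    rownames(m) <- d$gene_id
    m
  }
  expr <- to_mat(expr_path)
  clinical <- read_tsv(clinical_path, show_col_types = FALSE,
                       col_types = cols(sample_id = col_character()))
  protein <- if (is.null(protein_path)) NULL else to_mat(protein_path)
  bulk_cohort(expr, clinical, protein)
}

#' Write a bulk cohort to TSVs
#' @param x [bulk_cohort()] object.
#' @param expr_path,clinical_path,protein_path output paths.
#' @return `x`, invisibly.
#' @export
write_bulk <- function(x, expr_path, clinical_path, protein_path = NULL) {
  wr <- function(m, path) {
    write_tsv(dplyr::bind_cols(tibble(gene_id = rownames(m)), as_tibble(m)), path)
  }
  wr(x$expr, expr_path)
  write_tsv(x$clinical, clinical_path)
  if (!is.null(protein_path) && !is.null(x$protein)) wr(x$protein, protein_path)
  invisible(x)
}

#' Read a peak co-accessibility table
#' @param path TSV with columns peak1, peak2, coaccess.
#' @return tibble.
#' @export
read_coaccessibility <- function(path) {
  d <- read_tsv(path, show_col_types = FALSE)
  if (!all(c("peak1", "peak2", "coaccess") %in% names(d))) {
    err_fmt("%s: co-accessibility table needs peak1, peak2, coaccess", path)
  }
  d
}
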