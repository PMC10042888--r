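#' Per-sample differential expression tables for marker discovery
#'
#' Computes the three families of comparisons the tiered marker consensus
#' consumes: tumor vs each other cell type within each tumor sample, tumor vs
#' the combined non-tumor population within each tumor sample, and all tumor
#' cells vs non-tumor cells of the NAT samples. Samples need at least
#' `min_cells_group` tumor and comparison cells to enter a comparison;
#' criterion-1 comparisons skip cell types with fewer than `min_cells_type`
#' cells in that sample.
#'
#' @param norm [norm_matrix()] with `cell_meta` columns `sample_id`,
#'   `cell_type`, `group_label` (`"NAT"` marks normal-adjacent samples).
#' @param tumor_type,min_cells_type,min_cells_group see description.
#' @param min_pct,min_diff_pct detection pre-filters passed to
#'   [wilcoxon_de()].
#' @return list with elements `vs_type` (sample -> type -> `de_result`),
#'   `vs_nontumor` (sample -> `de_result`), `vs_nat` (`de_result` or `NULL`),
#'   and `samples_used`.
#' @export
tumor_marker_de_tables <- function(norm, tumor_type = "Tumor",
                                   min_cells_type = 10, min_cells_group = 3,
                                   min_pct = 0.1, min_diff_pct = 0.1) {
  meta <- norm$cell_meta
  tumor_samples <- unique(meta$sample_id[meta$cell_type == tumor_type])
  vs_type <- list(); vs_nontumor <- list(); used <- character()
  for (s in tumor_samples) {
    in_s <- meta$sample_id == s
    tum <- which(in_s & meta$cell_type == tumor_type)
    non <- which(in_s & meta$cell_type != tumor_type)
    if (length(tum) < min_cells_group || length(non) < min_cells_group) next
    used <- c(used, s)
    types <- setdiff(unique(meta$cell_type[in_s]), tumor_type)
    per_type <- list()
    for (ty in types) {
      other <- which(in_s & meta$cell_type == ty)
      if (length(other) < min_cells_type) next  # scarce types skipped
      per_type[[ty]] <- wilcoxon_de(norm, tum, other,
                                    min_pct = min_pct, min_diff_pct = min_diff_pct)
    }
    vs_type[[s]] <- per_type
    vs_nontumor[[s]] <- wilcoxon_de(norm, tum, non,
                                    min_pct = min_pct, min_diff_pct = min_diff_pct)
  }
  nat_cells <- which(meta$group_label %in% "NAT" & meta$cell_type != tumor_type)
  all_tumor <- which(meta$cell_type == tumor_type)
  vs_nat <- NULL
  if (length(nat_cells) >= min_cells_group && length(all_tumor) >= min_cells_group) {
    vs_nat <- wilcoxon_de(norm, all_tumor, nat_cells,
                          min_pct = min_pct, min_diff_pct = min_diff_pct)
  }
  list(vs_type = vs_type, vs_nontumor = vs_nontumor, vs_nat = vs_nat,
       samples_used = used)
}

#' Stage 1: tumor-cell-specific consensus across samples
#'
#' A gene passes when all three criteria hold: (c1) in at least one sample its
#' expression is significantly higher in tumor cells than in every other cell
#' type present (log fold change > 0, adjusted p < 0.05 against each type);
#' (c2) it is higher in tumor cells than the combined non-tumor population in
#' at least `frac_up` of samples and significantly so in at least `frac_sig`
#' of samples; (c3) it is higher in tumor cells than non-tumor cells of the
#' normal adjacent tissue. Fractions are computed over the samples with enough
#' cells to compare and use `>=` (9/10 samples passes a 90% threshold).
#'
#' @param de_tables output of [tumor_marker_de_tables()].
#' @param frac_up,frac_sig sample fractions for criterion 2 (defaults 0.9 and
#'   0.75).
#' @param p_cut adjusted p-value cutoff.
#' @return tibble with columns `gene`, `c1`, `c2`, `c3`, `stage1_pass`.
#' @export
stage1_tumor_specific <- function(de_tables, frac_up = 0.9, frac_sig = 0.75,
                                  p_cut = 0.05) {
  samples <- names(de_tables$vs_nontumor)
  if (!length(samples)) abort("no usable samples", class = "nephromics_stat_error")
  genes <- de_tables$vs_nontumor[[1]]$gene

  sig_up <- function(de) !is.na(de$p_adj) & de$p_adj < p_cut & de$lfc > 0
  # c1: exists a sample where gene is significantly up vs every type present
  c1 <- rep(FALSE, length(genes))
  for (s in samples) {
    tabs <- de_tables$vs_type[[s]]
    if (!length(tabs)) next
    ok <- Reduce(`&`, lapply(tabs, sig_up))
    c1 <- c1 | ok
  }
  # c2: up in >= frac_up of samples, significant in >= frac_sig
  up_mat <- vapply(samples, function(s) de_tables$vs_nontumor[[s]]$lfc > 0,
                   logical(length(genes)))
  sig_mat <- vapply(samples, function(s) sig_up(de_tables$vs_nontumor[[s]]),
                    logical(length(genes)))
  n_s <- length(samples)
  c2 <- rowSums(up_mat) / n_s >= frac_up & rowSums(sig_mat) / n_s >= frac_sig
  # c3: up in tumor vs NAT non-tumor cells
  c3 <- if (is.null(de_tables$vs_nat)) rep(NA, length(genes)) else de_tables$vs_nat$lfc > 0
  tibble(gene = genes, c1 = c1, c2 = c2, c3 = c3,
         stage1_pass = c1 & c2 & (is.na(c3) | c3))
}

#' Stage 2: exclusion of proximal tubule and epithelial programs
#'
#' Keeps stage-1 genes that are also significantly higher in tumor cells than
#' pooled NAT proximal tubule cells and than each listed epithelial cell type.
#'
#' @param stage1_genes character vector of stage-1 passing genes.
#' @param norm [norm_matrix()].
#' @param tumor_type tumor cell-type label.
#' @param epithelial_types cell types to exclude against (default `"PT"`).
#' @param p_cut adjusted p-value cutoff.
#' @return character vector of surviving genes.
#' @export
stage2_epithelial_exclusion <- function(stage1_genes, norm, tumor_type = "Tumor",
                                        epithelial_types = "PT", p_cut = 0.05) {
  if (!length(stage1_genes)) return(character())
  meta <- norm$cell_meta
  tum <- which(meta$cell_type == tumor_type)
  keep <- stage1_genes
  for (ty in epithelial_types) {
    cells <- which(meta$cell_type == ty & meta$group_label %in% "NAT")
    if (length(cells) < 3) cells <- which(meta$cell_type == ty)
    if (length(cells) < 3) {
      warn(sprintf("epithelial type '%s' has <3 cells; skipped", ty))
      next
    }
    de <- wilcoxon_de(norm, tum, cells, min_pct = 0.1, min_diff_pct = 0)
    ok <- de$gene[!is.na(de$p_adj) & de$p_adj < p_cut & de$lfc > 0]
    keep <- intersect(keep, ok)
  }
  keep
}

#' Stage 3: chromatin-accessibility support from gene activity
#'
#' Requires a linear fold of mean (de-logged) gene activity in tumor vs
#' non-tumor cells strictly greater than `fold_cut`. Genes absent from the
#' activity matrix are flagged missing and excluded.
#'
#' @param genes candidate genes.
#' @param activity_norm log-normalized gene-activity [norm_matrix()].
#' @param tumor_type tumor cell-type label.
#' @param fold_cut linear fold threshold (default 1, strict).
#' @return tibble with `gene`, `activity_fc`, `pass`.
#' @export
stage3_atac_support <- function(genes, activity_norm, tumor_type = "Tumor",
                                fold_cut = 1) {
  meta <- activity_norm$cell_meta
  tum <- meta$cell_type == tumor_type
  if (!any(tum) || all(tum)) abort("need tumor and non-tumor activity cells",
                                   class = "nephromics_stat_error")
  v <- activity_norm$values
  mean_t <- Matrix::rowSums(expm1_sp(v[, tum, drop = FALSE])) / sum(tum)
  mean_n <- Matrix::rowSums(expm1_sp(v[, !tum, drop = FALSE])) / sum(!tum)
  idx <- match(genes, activity_norm$gene_ids)
  fc <- ifelse(is.na(idx), NA_real_, mean_t[idx] / pmax(mean_n[idx], .Machine$double.eps))
  tibble(gene = genes, activity_fc = fc, pass = !is.na(fc) & fc > fold_cut)
}

#' Stage 4: bulk RNA and protein validation
#'
#' Two-sided rank-sum test of tumor vs NAT per gene on bulk expression and on
#' protein abundance, BH-corrected across the tested genes; a gene passes a
#' layer when it is higher in tumors with q < `q_cut`. Genes without a
#' protein row get `NA` for the protein flag.
#'
#' @param genes candidate genes.
#' @param bulk [bulk_cohort()].
#' @param q_cut BH-adjusted p cutoff (default 0.05).
#' @return tibble with `gene`, `bulk_rna_lfc`, `bulk_rna_q`, `bulk_rna_pass`,
#'   `protein_q`, `protein_pass`.
#' @export
stage4_bulk_validation <- function(genes, bulk, q_cut = 0.05) {
  tum <- bulk$clinical$tissue == "tumor"
  layer <- function(mat) {
    idx <- match(genes, rownames(mat))
    present <- which(!is.na(idx))
    p <- diff <- rep(NA_real_, length(genes))
    if (length(present)) {
      sub <- mat[idx[present], , drop = FALSE]
      p[present] <- rank_sum_rows(sub, which(tum))
      diff[present] <- rowMeans(sub[, tum, drop = FALSE]) -
        rowMeans(sub[, !tum, drop = FALSE])
    }
    q <- adjust_p(p, "BH")
    list(diff = diff, q = q, pass = ifelse(is.na(q), NA, q < q_cut & diff > 0))
  }
  rna <- layer(bulk$expr)
  prot <- if (is.null(bulk$protein)) {
    list(diff = rep(NA_real_, length(genes)), q = rep(NA_real_, length(genes)),
         pass = rep(NA, length(genes)))
  } else layer(bulk$protein)
  tibble(gene = genes, bulk_rna_lfc = rna$diff, bulk_rna_q = rna$q,
         bulk_rna_pass = rna$pass, protein_q = prot$q, protein_pass = prot$pass)
}

#' Tiered tumor-marker discovery across all evidence layers
#'
#' Runs the 4-stage consensus: (1) cross-sample tumor specificity, (2)
#' proximal-tubule/epithelial exclusion, (3) chromatin-accessibility support,
#' (4) bulk RNA (and protein) validation. `final_tier` is the number of
#' consecutive stages passed; the protein result is reported as a separate
#' flag. Stages without data (no activity / bulk input) cap the tier.
#'
#' @param norm log-normalized single-nucleus [norm_matrix()].
#' @param activity_norm optional gene-activity [norm_matrix()].
#' @param bulk optional [bulk_cohort()].
#' @param location optional tibble (`gene`, `location`) used to restrict
#'   stage-2 survivors to surface-annotated genes (rows with location
#'   `"surface"`); `NULL` disables the filter.
#' @param ... thresholds passed to the stage functions.
#' @return tibble of class `marker_report`: per-gene flags and `final_tier`.
#' @export
discover_tumor_markers <- function(norm, activity_norm = NULL, bulk = NULL,
                                   location = NULL, ...) {
  de <- tumor_marker_de_tables(norm, ...)
  s1 <- stage1_tumor_specific(de)
  genes1 <- s1$gene[s1$stage1_pass]
  genes2 <- stage2_epithelial_exclusion(genes1, norm)
  if (!is.null(location)) {
    genes2 <- intersect(genes2, location$gene[location$location == "surface"])
  }
  rep_tbl <- s1
  rep_tbl$stage2_pass <- rep_tbl$gene %in% genes2
  if (!is.null(activity_norm) && length(genes2)) {
    s3 <- stage3_atac_support(genes2, activity_norm)
    rep_tbl <- dplyr::left_join(rep_tbl, s3, by = "gene")
    rep_tbl$stage3_pass <- !is.na(rep_tbl$pass) & rep_tbl$pass
    rep_tbl$pass <- NULL
  } else {
    rep_tbl$activity_fc <- NA_real_
    rep_tbl$stage3_pass <- NA
  }
  genes3 <- rep_tbl$gene[isTRUE_v(rep_tbl$stage3_pass)]
  if (!is.null(bulk) && length(genes3)) {
    s4 <- stage4_bulk_validation(genes3, bulk)
    rep_tbl <- dplyr::left_join(rep_tbl, s4, by = "gene")
  } else {
    rep_tbl$bulk_rna_pass <- NA
    rep_tbl$protein_pass <- NA
  }
  tier <- integer(nrow(rep_tbl))
  tier[rep_tbl$stage1_pass] <- 1L
  tier[tier == 1L & rep_tbl$stage2_pass] <- 2L
  tier[tier == 2L & isTRUE_v(rep_tbl$stage3_pass)] <- 3L
  tier[tier == 3L & isTRUE_v(rep_tbl$bulk_rna_pass)] <- 4L
  rep_tbl$final_tier <- tier
  class(rep_tbl) <- c("marker_report", class(rep_tbl))
  rep_tbl
}

isTRUE_v <- function(x) !is.na(x) & x

#' Top cell-type marker genes by one-vs-rest rank-sum test
#'
#' Per cell type, tests the type's cells against all other cells and returns
#' the top `k` positively enriched genes ordered by p-value, then descending
#' fold change, then gene id (deterministic under ties). Shorter lists are
#' returned (with a message) when fewer genes pass.
#'
#' @param norm [norm_matrix()].
#' @param k markers per type (default 100).
#' @param types cell types to profile (default: all in `cell_meta`).
#' @return named list of character vectors.
#' @export
celltype_top_markers <- function(norm, k = 100, types = NULL) {
  meta <- norm$cell_meta
  types <- types %||% sort(unique(meta$cell_type[!is.na(meta$cell_type)]))
  out <- list()
  for (ty in types) {
    cells <- which(meta$cell_type == ty)
    de <- wilcoxon_de(norm, cells, which(meta$cell_type != ty),
                      min_pct = 0.1, min_diff_pct = 0)
    pos <- de[!is.na(de$p) & de$lfc > 0, ]
    pos <- pos[order(pos$p, -pos$lfc, pos$gene), ]
    if (nrow(pos) < k) {
      rlang::inform(sprintf("cell type '%s': only %d positive markers (k = %d)",
                            ty, nrow(pos), k))
    }
    out[[ty]] <- head(pos$gene, k)
  }
  out
}

#' Pairwise correlation of cell groups over a united marker list
#'
#' Pearson correlation of per-group average (de-logged) expression restricted
#' to the union of the given marker lists.
#'
#' @param mean_expr genes-by-groups matrix from [group_mean_expression()].
#' @param marker_lists list of character vectors (e.g. from
#'   [celltype_top_markers()]).
#' @return symmetric groups-by-groups correlation matrix with unit diagonal.
#' @export
celltype_correlation <- function(mean_expr, marker_lists) {
  genes <- intersect(unique(unlist(marker_lists)), rownames(mean_expr))
  if (length(genes) < 3) abort("need at least 3 marker genes present",
                               class = "nephromics_stat_error")
  cor(mean_expr[genes, , drop = FALSE])
}
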