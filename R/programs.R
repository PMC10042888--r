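#' Per-subcluster positive differentially expressed genes
#'
#' One-vs-rest rank-sum DE of each tumor subcluster against the other tumor
#' cells of the same sample; only positively enriched, significant genes are
#' kept. Clusters with fewer than `min_cells` cells are skipped (recorded in
#' the `skipped` attribute).
#'
#' @param norm [norm_matrix()] whose `cell_meta` has `cluster_id` labels on
#'   tumor cells.
#' @param tumor_type tumor cell-type label.
#' @param min_cells minimum cells per scored cluster (default 50).
#' @param p_cut adjusted p cutoff (default 0.05).
#' @return named list (cluster id -> character vector of DEGs, ordered by
#'   p then fold change then gene id) with attribute `skipped`.
#' @export
subcluster_degs <- function(norm, tumor_type = "Tumor", min_cells = 50,
                            p_cut = 0.05) {
  meta <- norm$cell_meta
  tum <- meta$cell_type == tumor_type & !is.na(meta$cluster_id)
  out <- list(); skipped <- character()
  for (s in unique(meta$sample_id[tum])) {
    in_s <- tum & meta$sample_id == s
    clusters <- sort(unique(meta$cluster_id[in_s]))
    if (length(clusters) < 2) next
    for (cl in clusters) {
      cells <- which(in_s & meta$cluster_id == cl)
      rest <- which(in_s & meta$cluster_id != cl)
      if (length(cells) < min_cells) { skipped <- c(skipped, cl); next }
      de <- wilcoxon_de(norm, cells, rest, min_pct = 0.1, min_diff_pct = 0)
      pos <- de[!is.na(de$p_adj) & de$p_adj < p_cut & de$lfc > 0, ]
      pos <- pos[order(pos$p, -pos$lfc, pos$gene), ]
      out[[cl]] <- pos$gene
    }
  }
  attr(out, "skipped") <- skipped
  out
}

#' Average de-logged expression per tumor subcluster
#'
#' Convenience wrapper around [group_mean_expression()] restricted to cells
#' carrying a cluster label.
#'
#' @param norm [norm_matrix()].
#' @param min_cells keep only clusters with at least this many cells.
#' @return list with `mean_expr` (genes x clusters), `cluster_meta` tibble
#'   (`cluster_id`, `sample_id`, `cell_type`, `n_cells`).
#' @export
cluster_mean_expression <- function(norm, min_cells = 50) {
  keep <- !is.na(norm$cell_meta$cluster_id)
  sub <- subset_cells(norm, keep)
  cm <- sub$cell_meta |>
    dplyr::count(.data$cluster_id, .data$sample_id, .data$cell_type,
                 name = "n_cells") |>
    dplyr::filter(.data$n_cells >= min_cells)
  sub <- subset_cells(sub, sub$cell_meta$cluster_id %in% cm$cluster_id)
  me <- group_mean_expression(sub, "cluster_id")
  cm <- cm[match(colnames(me), cm$cluster_id), ]
  list(mean_expr = me, cluster_meta = cm)
}

#' Pathway activity scores per tumor subcluster
#'
#' For each gene set, restricts to the set's members among the subcluster
#' DEGs, z-scales each gene's average expression across all clusters (mean 0,
#' sd 1), and averages the scaled values: the score of a cluster for a set is
#' the mean scaled expression of the set's DEGs. Genes with zero variance
#' across clusters are dropped with a warning; sets with no DEGs present
#' score `NA`.
#'
#' @param mean_expr genes-by-clusters matrix (see [cluster_mean_expression()]).
#' @param sets [gene_sets()] collection.
#' @param degs per-cluster DEG lists from [subcluster_degs()] (their union
#'   defines the DEG pool), or a plain character vector.
#' @param cluster_meta optional tibble carried into the result.
#' @return object of class `score_matrix`: list with `scores`
#'   (clusters x sets), `cluster_meta`, `genes_used`.
#' @export
pathway_scores <- function(mean_expr, sets, degs, cluster_meta = NULL) {
  pool <- if (is.list(degs)) unique(unlist(degs)) else unique(degs)
  scores <- matrix(NA_real_, ncol(mean_expr), length(sets),
                   dimnames = list(colnames(mean_expr), names(sets)))
  genes_used <- list()
  for (nm in names(sets)) {
    genes <- intersect(intersect(sets[[nm]], pool), rownames(mean_expr))
    if (!length(genes)) {
      rlang::inform(sprintf("set '%s': no DEGs present; score is NA", nm))
      genes_used[[nm]] <- character()
      next
    }
    z <- scale_rows(mean_expr[genes, , drop = FALSE], context = nm)
    genes_used[[nm]] <- rownames(z)
    if (nrow(z)) scores[, nm] <- colMeans(z)
  }
  structure(list(scores = scores, cluster_meta = cluster_meta,
                 genes_used = genes_used),
            class = "score_matrix")
}

scale_rows <- function(m, context = "") {
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  drop <- sd == 0
  if (any(drop)) {
    warn(sprintf("%s: dropped %d zero-variance gene(s) from scoring",
                 context, sum(drop)))
    m <- m[!drop, , drop = FALSE]; mu <- mu[!drop]; sd <- sd[!drop]
  }
  (m - mu) / sd
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix> %d clusters x %d sets\n",
              nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

#' Quantile-rule module enrichment of tumor subclusters
#'
#' A cluster is enriched in a module when its score exceeds the upper
#' `upper_q` quantile (type-7, linear interpolation) for every member set of
#' the module; an optional epithelial constraint additionally requires the
#' cluster's epithelial score to fall below the `epi_lower_q` quantile.
#'
#' @param sm [pathway_scores()] result.
#' @param module character vector of member set names.
#' @param upper_q quantile the score must exceed (default 0.75; the
#'   mTOR-style strict rule uses 0.90).
#' @param epithelial_scores optional named numeric vector (per cluster).
#' @param epi_lower_q quantile the epithelial score must fall below.
#' @return character vector of enriched cluster ids.
#' @export
module_enrichment <- function(sm, module, upper_q = 0.75,
                              epithelial_scores = NULL, epi_lower_q = 0.2) {
  stopifnot(all(module %in% colnames(sm$scores)))
  ok <- rep(TRUE, nrow(sm$scores))
  for (nm in module) {
    col <- sm$scores[, nm]
    ok <- ok & !is.na(col) & col > quantile(col, upper_q, na.rm = TRUE, type = 7)
  }
  if (!is.null(epithelial_scores)) {
    epi <- epithelial_scores[rownames(sm$scores)]
    ok <- ok & !is.na(epi) & epi < quantile(epithelial_scores, epi_lower_q,
                                            na.rm = TRUE, type = 7)
  }
  rownames(sm$scores)[ok]
}

#' Epithelial scores and Epi-H/M/L/EMT group assignment
#'
#' Scores are computed like pathway scores but z-scaled across both tumor and
#' proximal tubule clusters. Labels (for tumor clusters only) follow the
#' quantile bands of the tumor clusters' scores: above the 70% quantile is
#' Epi-H; strictly between the 40% and 70% quantiles is Epi-M; EMT-designated
#' clusters are labeled EMT regardless of band; everything else is Epi-L.
#' The four labels partition the tumor clusters.
#'
#' @param mean_expr genes-by-clusters matrix including tumor and PT clusters.
#' @param epithelial_markers epithelial/PT marker genes (those also
#'   down-regulated in EMT-enriched clusters, per the construction upstream).
#' @param tumor_clusters character vector of tumor cluster ids (columns of
#'   `mean_expr` not listed are treated as PT clusters and are scored but not
#'   labeled).
#' @param emt_clusters cluster ids designated EMT (e.g. from
#'   [module_enrichment()]).
#' @param hi_q,lo_q quantile bounds for Epi-H and Epi-M (defaults 0.70/0.40).
#' @return tibble with `cluster_id`, `epithelial_score`, `group` (`NA` for PT
#'   clusters).
#' @export
epithelial_scores_and_groups <- function(mean_expr, epithelial_markers,
                                         tumor_clusters, emt_clusters = character(),
                                         hi_q = 0.70, lo_q = 0.40) {
  genes <- intersect(epithelial_markers, rownames(mean_expr))
  if (!length(genes)) abort("no epithelial markers present",
                            class = "nephromics_stat_error")
  z <- scale_rows(mean_expr[genes, , drop = FALSE], context = "epithelial score")
  score <- colMeans(z)
  tum <- intersect(names(score), tumor_clusters)
  qs <- quantile(score[tum], c(lo_q, hi_q), type = 7)
  grp <- rep(NA_character_, length(score))
  names(grp) <- names(score)
  grp[tum] <- "Epi-L"
  grp[tum][score[tum] > qs[2]] <- "Epi-H"
  grp[tum][score[tum] < qs[2] & score[tum] > qs[1]] <- "Epi-M"
  grp[intersect(tum, emt_clusters)] <- "EMT"
  tibble(cluster_id = names(score), epithelial_score = unname(score),
         group = unname(grp))
}

#' Association of subcluster scores with tumor stage
#'
#' Takes the highest score across a patient's tumor subclusters for each set,
#' then compares high-stage (III/IV) vs low-stage (I/II) patients with a
#' two-sided rank-sum test, BH-corrected across sets.
#'
#' @param sm [pathway_scores()] result whose `cluster_meta` has `sample_id`.
#' @param clinical tibble with `sample_id` and `stage` (I-IV).
#' @return tibble with `set`, `n_low`, `n_high`, `p`, `p_adj`, `direction`
#'   (+1 when high-stage scores are larger).
#' @export
stage_association <- function(sm, clinical) {
  if (is.null(sm$cluster_meta)) abort("score matrix lacks cluster metadata",
                                      class = "nephromics_config_error")
  meta <- dplyr::left_join(sm$cluster_meta, clinical, by = "sample_id")
  high <- meta$stage %in% c("III", "IV")
  low <- meta$stage %in% c("I", "II")
  rows <- purrr::map_dfr(colnames(sm$scores), function(nm) {
    per_pat <- tibble(sample_id = meta$sample_id, score = sm$scores[, nm],
                      grp = ifelse(high, "high", ifelse(low, "low", NA))) |>
      dplyr::filter(!is.na(.data$grp), !is.na(.data$score)) |>
      dplyr::group_by(.data$sample_id, .data$grp) |>
      dplyr::summarise(score = max(.data$score), .groups = "drop")
    a <- per_pat$score[per_pat$grp == "high"]
    b <- per_pat$score[per_pat$grp == "low"]
    if (length(a) < 2 || length(b) < 2) {
      abort(sprintf("set '%s': need >=2 patients per stage group", nm),
            class = "nephromics_stat_error")
    }
    p <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
    if (is.nan(p)) p <- 1  # fully tied groups carry no evidence
    tibble(set = nm, n_low = length(b), n_high = length(a), p = p,
           direction = sign(stats::median(a) - stats::median(b)))
  })
  rows$p_adj <- adjust_p(rows$p, "BH")
  rows
}
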