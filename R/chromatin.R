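#' @importFrom GenomicRanges GRanges findOverlaps distance
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

peaks_to_gr <- function(peaks) {
  # peaks are 0-based half-open; GRanges is 1-based inclusive
  GRanges(peaks$chrom, IRanges(peaks$start + 1, peaks$end))
}

#' Resize peaks to a fixed width centered on the summit
#'
#' @param peaks peak tibble (see [peak_table()]).
#' @param width target width in bp (default 501).
#' @return peak tibble with every interval `width` bp, summit-centered.
#' @export
resize_peaks <- function(peaks, width = 501) {
  peaks <- peak_table(peaks)
  half <- (width - 1) %/% 2
  out <- dplyr::mutate(peaks,
                       start = .data$summit - half,
                       end = .data$summit + (width - half),
                       peak_id = sprintf("%s:%d-%d", .data$chrom, .data$start, .data$end))
  peak_table(out, resized = width == 501)
}

#' Iterative removal of overlapping peaks by signal
#'
#' Greedy retention in descending score order: a peak is kept unless it
#' overlaps an already-kept peak of greater signal. Ties are broken by
#' (chrom, start, peak id) so the result is deterministic. The output is
#' pairwise non-overlapping.
#'
#' @param peaks peak tibble.
#' @return peak tibble (original row order of the retained peaks).
#' @export
dedup_peaks <- function(peaks) {
  peaks <- peak_table(peaks)
  n <- nrow(peaks)
  if (n <= 1) return(peaks)
  ord <- order(-peaks$score, peaks$chrom, peaks$start, peaks$peak_id)
  hits <- findOverlaps(peaks_to_gr(peaks), drop.self = TRUE)
  nb <- split(subjectHits(hits), queryHits(hits))
  removed <- logical(n)
  kept <- logical(n)
  for (i in ord) {
    if (removed[i]) next
    kept[i] <- TRUE
    js <- nb[[as.character(i)]]
    if (!is.null(js)) removed[js] <- TRUE
  }
  peaks[kept, ]
}

#' Resize to 501 bp and deduplicate a raw peak set
#'
#' @param peaks raw peak tibble with summits and scores.
#' @return non-overlapping 501-bp peak tibble.
#' @export
resize_and_dedup_peaks <- function(peaks) dedup_peaks(resize_peaks(peaks))

#' Gene activity from a peak-count matrix
#'
#' Sums, per cell, the fragment counts of peaks overlapping each gene's
#' activity window: the gene body extended 2 kb upstream (strand-aware).
#'
#' @param pm [peak_matrix()].
#' @param genes gene-model tibble (1-based inclusive coordinates).
#' @param upstream upstream extension in bp (default 2000).
#' @return [sn_counts()] of gene-by-cell activity counts (same cells and
#'   metadata as `pm`).
#' @export
gene_activity <- function(pm, genes, upstream = 2000) {
  genes <- gene_model(genes)
  win_start <- ifelse(genes$strand == "+", genes$start - upstream, genes$start)
  win_end <- ifelse(genes$strand == "+", genes$end, genes$end + upstream)
  gr_g <- GRanges(genes$chrom, IRanges(pmax(win_start, 1), win_end))
  hits <- findOverlaps(gr_g, peaks_to_gr(pm$peaks))
  ind <- Matrix::sparseMatrix(i = queryHits(hits), j = subjectHits(hits), x = 1,
                              dims = c(nrow(genes), nrow(pm$peaks)))
  act <- ind %*% pm$counts
  sn_counts(act, genes$gene_id, pm$cell_ids, pm$cell_meta)
}

# Fast per-feature logistic LRT against a shared null model.
lr_pvals_matrix <- function(features, y, covariates = NULL) {
  lr_group_test(features, y, covariates)$p
}

#' Consistency-filtered differential accessible chromatin regions
#'
#' Per mutant sample, tests every peak's normalized accessibility in that
#' sample's tumor cells against pooled tumor cells of the control samples
#' with a logistic likelihood-ratio test using per-cell FRiP as a latent
#' covariate; p-values are Bonferroni-adjusted over all peaks. A peak is a
#' consensus DACR when it is significant in at least `min_frac` of the
#' comparisons and its fold direction agrees across all comparisons (a zero
#' fold counts as inconsistent). When per-sample CNV values are supplied, a
#' pooled mutant-vs-control test with FRiP and the peak's CNV value as latent
#' covariates is run on the consensus peaks, and peaks no longer significant
#' are removed.
#'
#' @param pm [peak_matrix()] with `sample_id`, `cell_type`, `frip` metadata.
#' @param mutant_samples,control_samples sample id vectors (>= 2 mutant
#'   samples required).
#' @param cell_type cells used in the comparisons (default `"Tumor"`).
#' @param cnv_values optional peaks-by-samples matrix of log2 copy ratios.
#' @param p_cut adjusted p cutoff (default 0.05).
#' @param min_frac minimum fraction of significant comparisons (default 0.5).
#' @param pseudocount added to group mean accessibility before the fold.
#' @return tibble of class `dacr_result`: per peak `n_significant`,
#'   `n_compared`, `consistent_direction`, `direction`, `cnv_corrected_pass`,
#'   `final_pass`, plus a `p_adj` matrix attribute (peaks x comparisons).
#' @export
dacr_consensus <- function(pm, mutant_samples, control_samples,
                           cell_type = "Tumor", cnv_values = NULL,
                           p_cut = 0.05, min_frac = 0.5, pseudocount = 0.01) {
  if (length(mutant_samples) < 2) {
    abort("consensus undefined for < 2 mutant samples", class = "nephromics_stat_error")
  }
  meta <- pm$cell_meta
  norm <- lognormalize(pm)
  v <- norm$values
  n_pk <- nrow(v)
  ctrl <- which(meta$sample_id %in% control_samples & meta$cell_type %in% cell_type)
  if (length(ctrl) < 3) abort("too few control cells", class = "nephromics_stat_error")
  ctrl_dense <- as.matrix(v[, ctrl, drop = FALSE])
  mean_ctrl <- rowMeans(expm1(ctrl_dense))

  p_mat <- matrix(NA_real_, n_pk, length(mutant_samples),
                  dimnames = list(pm$gene_ids, mutant_samples))
  dir_mat <- p_mat
  for (s in mutant_samples) {
    mut <- which(meta$sample_id == s & meta$cell_type %in% cell_type)
    if (length(mut) < 3) next
    feats <- cbind(as.matrix(v[, mut, drop = FALSE]), ctrl_dense)
    y <- rep(c(1, 0), c(length(mut), length(ctrl)))
    frip <- c(meta$frip[mut], meta$frip[ctrl])
    p_mat[, s] <- lr_pvals_matrix(feats, y, cbind(frip = frip))
    mean_mut <- rowMeans(expm1(feats[, seq_along(mut), drop = FALSE]))
    dir_mat[, s] <- sign(log((mean_mut + pseudocount) / (mean_ctrl + pseudocount)))
  }
  compared <- colSums(!is.na(p_mat)) > 0
  if (sum(compared) < 2) abort("fewer than 2 usable mutant comparisons",
                               class = "nephromics_stat_error")
  p_adj <- pmin(p_mat * n_pk, 1)  # Bonferroni using all peaks
  sig <- !is.na(p_adj) & p_adj < p_cut
  n_sig <- rowSums(sig, na.rm = TRUE)
  n_cmp <- rowSums(!is.na(p_adj))
  consistent <- apply(dir_mat, 1, function(d) {
    d <- d[!is.na(d)]
    length(d) > 0 && all(d != 0) && length(unique(d)) == 1
  })
  direction <- ifelse(consistent, dir_mat[, which(compared)[1]], 0)
  pre_pass <- n_cmp > 0 & (n_sig / pmax(n_cmp, 1)) >= min_frac & consistent

  cnv_pass <- rep(NA, n_pk)
  if (!is.null(cnv_values)) {
    mut_all <- which(meta$sample_id %in% mutant_samples & meta$cell_type %in% cell_type)
    cells <- c(mut_all, ctrl)
    y <- rep(c(1, 0), c(length(mut_all), length(ctrl)))
    frip <- meta$frip[cells]
    samp <- meta$sample_id[cells]
    idx <- which(pre_pass)
    cnv_pass[idx] <- vapply(idx, function(i) {
      cnv_cell <- cnv_values[i, samp]
      cnv_cell[is.na(cnv_cell)] <- 0
      p <- lr_group_test(as.numeric(v[i, cells]), y,
                         cbind(frip = frip, cnv = as.numeric(cnv_cell)))$p
      min(1, p * n_pk) < p_cut
    }, logical(1))
  }
  final <- pre_pass & (is.na(cnv_pass) | cnv_pass)
  out <- tibble(peak_id = pm$gene_ids, n_significant = n_sig, n_compared = n_cmp,
                consistent_direction = consistent, direction = direction,
                cnv_corrected_pass = cnv_pass, final_pass = final)
  attr(out, "p_adj") <- p_adj
  class(out) <- c("dacr_result", class(out))
  out
}

#' Promoter intervals for a gene model
#'
#' The promoter is (-1000, +100) around the transcription start site,
#' strand-aware, in 1-based inclusive coordinates: `[tss - 1000, tss + 100]`
#' on the + strand and `[tss - 100, tss + 1000]` on the - strand.
#'
#' @param genes gene-model tibble.
#' @param upstream,downstream window sizes (defaults 1000 / 100).
#' @return tibble with `gene_id`, `chrom`, `strand`, `prom_start`, `prom_end`,
#'   `tss`.
#' @export
annotate_promoters <- function(genes, upstream = 1000, downstream = 100) {
  genes <- gene_model(genes)
  tibble(
    gene_id = genes$gene_id, chrom = genes$chrom, strand = genes$strand,
    prom_start = pmax(1, ifelse(genes$strand == "+",
                                genes$tss - upstream, genes$tss - downstream)),
    prom_end = ifelse(genes$strand == "+",
                      genes$tss + downstream, genes$tss + upstream),
    tss = genes$tss
  )
}

#' Classify peaks as promoter or distal and assign the nearest gene
#'
#' A peak is promoter-class when it overlaps any promoter interval. The
#' nearest gene is the one whose TSS is closest to the peak (distance 0 when
#' the TSS falls inside the peak); ties are broken by gene id.
#'
#' @param peaks peak tibble (0-based half-open).
#' @param genes gene-model tibble.
#' @param ... passed to [annotate_promoters()].
#' @return tibble: `peak_id`, `class` (`promoter`/`distal`), `nearest_gene`,
#'   `tss_distance`.
#' @export
classify_peaks <- function(peaks, genes, ...) {
  peaks <- peak_table(peaks)
  prom <- annotate_promoters(genes, ...)
  gr_p <- peaks_to_gr(peaks)
  gr_prom <- GRanges(prom$chrom, IRanges(prom$prom_start, prom$prom_end))
  is_prom <- rep(FALSE, nrow(peaks))
  is_prom[unique(queryHits(findOverlaps(gr_p, gr_prom)))] <- TRUE
  gr_tss <- GRanges(prom$chrom, IRanges(prom$tss, prom$tss))
  nearest_gene <- rep(NA_character_, nrow(peaks))
  tss_dist <- rep(NA_real_, nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == ch)
    gi <- which(prom$chrom == ch)
    if (!length(gi)) next
    for (i in pi) {
      d <- pmax(0, pmax(prom$tss[gi] - peaks$end[i], (peaks$start[i] + 1) - prom$tss[gi]))
      ord <- order(d, prom$gene_id[gi])
      nearest_gene[i] <- prom$gene_id[gi][ord[1]]
      tss_dist[i] <- d[ord[1]]
    }
  }
  tibble(peak_id = peaks$peak_id, class = ifelse(is_prom, "promoter", "distal"),
         nearest_gene = nearest_gene, tss_distance = tss_dist)
}

# ---- motif scanning ---------------------------------------------------------

pwm_log_odds <- function(p, min_bits = -20) {
  lo <- log2(p$matrix / p$background)
  lo[!is.finite(lo) | lo < min_bits] <- min_bits
  lo
}

#' Score threshold for a PWM at a background p-value
#'
#' Computes the exact distribution of the log-odds score of a random window
#' under the i.i.d. background model by dynamic programming over scores
#' discretized to `delta`-bit bins, and returns the smallest score whose
#' exceedance probability is at most `p_threshold`.
#'
#' @param p [pwm()] object.
#' @param p_threshold background exceedance probability (default 5e-5).
#' @param delta score bin width in bits (default 1e-3).
#' @return threshold score in bits.
#' @export
pwm_score_threshold <- function(p, p_threshold = 5e-5, delta = 1e-3) {
  lo <- round(pwm_log_odds(p) / delta)
  L <- ncol(lo)
  offset <- sum(apply(lo, 2, min))
  width <- sum(apply(lo, 2, function(col) max(col) - min(col))) + 1L
  dist <- numeric(width); dist[1] <- 1
  pos <- 1L
  for (j in seq_len(L)) {
    col <- lo[, j] - min(lo[, j])
    new <- numeric(width)
    for (b in 1:4) {
      s <- col[b]
      idx <- seq_len(pos)
      new[idx + s] <- new[idx + s] + dist[idx] * p$background[b]
    }
    dist <- new
    pos <- pos + max(col)
  }
  tail_p <- rev(cumsum(rev(dist)))
  k <- which(tail_p <= p_threshold & dist > 0)  # smallest achievable score
  if (!length(k)) return(Inf)
  (min(k) - 1 + offset) * delta
}

rc_pwm <- function(p) {
  m <- p$matrix[4:1, rev(seq_len(ncol(p$matrix))), drop = FALSE]
  rownames(m) <- c("A", "C", "G", "T")
  pwm(m, p$motif_id, background = p$background[4:1])
}

scan_one_strand <- function(lo, code, threshold) {
  L <- ncol(lo)
  n <- length(code)
  if (n < L) return(integer())
  nw <- n - L + 1L
  sc <- numeric(nw)
  ok <- rep(TRUE, nw)
  for (j in seq_len(L)) {
    cj <- code[j:(j + nw - 1L)]
    bad <- is.na(cj)
    ok <- ok & !bad
    cj[bad] <- 1L
    sc <- sc + lo[cbind(cj, j)]
  }
  which(ok & sc >= threshold) |> (\(i) {attr(i, "score") <- sc[i]; i})()
}

#' Scan sequences for PWM motif hits
#'
#' Slides each PWM over both strands of every sequence, scoring windows by
#' summed log2-odds against the background; windows containing `N` are
#' skipped. The reporting threshold is the exact background-distribution
#' score at `p_threshold` (see [pwm_score_threshold()]). Minus-strand hits
#' are reported at their forward-strand offset.
#'
#' @param pwms list of [pwm()] objects (or a single one).
#' @param seqs named character vector of sequences.
#' @param p_threshold background exceedance probability (default 5e-5).
#' @param delta DP bin width in bits.
#' @return tibble of class `motif_hits`: `motif_id`, `seq_id`, `offset`
#'   (0-based), `strand`, `score` (bits).
#' @export
scan_motifs <- function(pwms, seqs, p_threshold = 5e-5, delta = 1e-3) {
  if (inherits(pwms, "pwm")) pwms <- setNames(list(pwms), pwms$motif_id)
  codes <- lapply(seqs, function(s) {
    match(strsplit(toupper(s), "")[[1]], c("A", "C", "G", "T"))
  })
  rows <- list()
  for (p in pwms) {
    thr <- pwm_score_threshold(p, p_threshold, delta)
    lo_f <- pwm_log_odds(p)
    lo_r <- pwm_log_odds(rc_pwm(p))
    for (nm in names(seqs)) {
      for (st in c("+", "-")) {
        lo <- if (st == "+") lo_f else lo_r
        hit <- scan_one_strand(lo, codes[[nm]], thr)
        if (length(hit)) {
          rows[[length(rows) + 1L]] <- tibble(
            motif_id = p$motif_id, seq_id = nm, offset = as.integer(hit) - 1L,
            strand = st, score = as.numeric(attr(hit, "score"))
          )
        }
      }
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble(motif_id = character(), seq_id = character(), offset = integer(),
           strand = character(), score = numeric())
  class(out) <- c("motif_hits", class(out))
  out
}

#' Map motif hits in DACRs to target genes
#'
#' Restricts to genes whose promoter overlaps at least one DACR, then links
#' each motif hit found in one of the gene's DACRs to the gene. The gene's
#' DACRs are those overlapping its promoter plus peaks co-accessible with
#' them at `coaccess_cut` or above (labeled enhancer). A hit is a promoter
#' motif when its absolute genomic interval overlaps the promoter window,
#' and a distant motif otherwise.
#'
#' @param dacr_peaks peak tibble of the DACRs (hit `seq_id`s must match
#'   their `peak_id`s).
#' @param genes gene-model tibble of the candidate (e.g. differentially
#'   expressed) genes.
#' @param hits [scan_motifs()] result over the DACR sequences.
#' @param motif_lengths named integer vector (motif id -> length) used to
#'   place hit intervals; defaults to 1 bp at the hit offset.
#' @param coaccess optional tibble (`peak1`, `peak2`, `coaccess`).
#' @param coaccess_cut enhancer co-accessibility cutoff (default 0.25,
#'   inclusive).
#' @return tibble: `motif_id`, `gene_id`, `peak_id`, `category`
#'   (`promoter`/`distant`), `enhancer`.
#' @export
map_motifs_to_genes <- function(dacr_peaks, genes, hits, motif_lengths = NULL,
                                coaccess = NULL, coaccess_cut = 0.25) {
  dacr_peaks <- peak_table(dacr_peaks)
  prom <- annotate_promoters(genes)
  gr_d <- peaks_to_gr(dacr_peaks)
  gr_prom <- GRanges(prom$chrom, IRanges(prom$prom_start, prom$prom_end))
  ov <- suppressWarnings(findOverlaps(gr_prom, gr_d))
  if (!length(ov)) return(tibble(motif_id = character(), gene_id = character(),
                                 peak_id = character(), category = character(),
                                 enhancer = logical()))
  links <- tibble(gene_id = prom$gene_id[queryHits(ov)],
                  peak_id = dacr_peaks$peak_id[subjectHits(ov)],
                  enhancer = FALSE)
  if (!is.null(coaccess)) {
    pairs <- dplyr::bind_rows(
      coaccess[, c("peak1", "peak2", "coaccess")],
      setNames(coaccess[, c("peak2", "peak1", "coaccess")],
               c("peak1", "peak2", "coaccess"))
    ) |> dplyr::filter(.data$coaccess >= coaccess_cut)
    enh <- dplyr::inner_join(links[, c("gene_id", "peak_id")], pairs,
                             by = c(peak_id = "peak1")) |>
      dplyr::transmute(gene_id = .data$gene_id, peak_id = .data$peak2,
                       enhancer = TRUE) |>
      dplyr::filter(.data$peak_id %in% dacr_peaks$peak_id)
    links <- dplyr::bind_rows(links, enh) |>
      dplyr::group_by(.data$gene_id, .data$peak_id) |>
      dplyr::summarise(enhancer = any(.data$enhancer) && !any(!.data$enhancer),
                       .groups = "drop")
  }
  h <- dplyr::inner_join(hits, links, by = c(seq_id = "peak_id"),
                         relationship = "many-to-many")
  if (!nrow(h)) return(tibble(motif_id = character(), gene_id = character(),
                              peak_id = character(), category = character(),
                              enhancer = logical()))
  pk_idx <- match(h$seq_id, dacr_peaks$peak_id)
  len <- if (is.null(motif_lengths)) rep(1L, nrow(h)) else motif_lengths[h$motif_id]
  hit_start <- dacr_peaks$start[pk_idx] + h$offset + 1  # 1-based
  hit_end <- hit_start + len - 1
  gi <- match(h$gene_id, prom$gene_id)
  in_prom <- unname(dacr_peaks$chrom[pk_idx] == prom$chrom[gi] &
    hit_end >= prom$prom_start[gi] & hit_start <= prom$prom_end[gi])
  dplyr::distinct(tibble(
    motif_id = h$motif_id, gene_id = h$gene_id, peak_id = h$seq_id,
    category = ifelse(in_prom, "promoter", "distant"), enhancer = h$enhancer
  ))
}

# ---- motif deviations -------------------------------------------------------

#' Simplified per-cell motif deviation z-scores
#'
#' For each motif, the expected fragment count of a cell is its total count
#' times the summed popularity (fraction of cells with nonzero count) of the
#' motif's peaks over the popularity of all peaks; the raw deviation is
#' (observed - expected) / expected. Deviations are standardized against
#' `n_background` background peak sets sampled within popularity deciles
#' (mean-accessibility matching; GC matching is not attempted).
#'
#' @param pm [peak_matrix()].
#' @param motif_peaks named list (motif id -> peak ids) or a
#'   [scan_motifs()] tibble whose `seq_id`s are peak ids.
#' @param n_background background set count (default 50).
#' @param seed RNG seed for background sampling.
#' @param standardize return background-standardized z-scores (default);
#'   `FALSE` returns the raw relative deviations (a motif covering every peak
#'   has raw deviation identically zero).
#' @return motifs-by-cells matrix of deviation scores.
#' @export
motif_deviation_scores <- function(pm, motif_peaks, n_background = 50, seed = 1,
                                   standardize = TRUE) {
  if (is.data.frame(motif_peaks)) {
    motif_peaks <- split(motif_peaks$seq_id, motif_peaks$motif_id)
    motif_peaks <- lapply(motif_peaks, unique)
  }
  counts <- pm$counts
  pop <- Matrix::rowMeans(counts > 0)
  totals <- Matrix::colSums(counts)
  pop_total <- sum(pop)
  decile <- cut(rank(pop, ties.method = "first"), breaks = 10, labels = FALSE)
  by_dec <- split(seq_along(pop), decile)
  raw_dev <- function(idx) {
    obs <- Matrix::colSums(counts[idx, , drop = FALSE])
    ex <- totals * sum(pop[idx]) / pop_total
    ifelse(ex > 0, (obs - ex) / ex, 0)
  }
  withr::with_seed(seed, {
    out <- matrix(0, length(motif_peaks), ncol(counts),
                  dimnames = list(names(motif_peaks), pm$cell_ids))
    for (m in names(motif_peaks)) {
      idx <- match(motif_peaks[[m]], pm$gene_ids)
      idx <- idx[!is.na(idx)]
      if (!length(idx)) next
      raw <- raw_dev(idx)
      if (!standardize) { out[m, ] <- raw; next }
      bg <- vapply(seq_len(n_background), function(b) {
        bidx <- vapply(idx, function(i) {
          pool <- by_dec[[decile[i]]]
          pool[sample.int(length(pool), 1)]
        }, integer(1))
        raw_dev(bidx)
      }, numeric(ncol(counts)))
      mu <- rowMeans(bg)
      sd <- apply(bg, 1, stats::sd)
      out[m, ] <- ifelse(sd > 0, (raw - mu) / sd, 0)
    }
    out
  })
}

#' Per-sample differential motif accessibility with consistency tiers
#'
#' For each sample, compares the deviation z-scores of that sample's tumor
#' cells against the pooled reference cells with a two-sided rank-sum test
#' (BH correction across motifs per comparison). Motifs significant with a
#' common direction in at least half of the samples pass the `half` tier;
#' those significant in every sample pass the strict `all` tier.
#'
#' @param dev motifs-by-cells deviation matrix.
#' @param cell_meta tibble with `sample_id` and `cell_type` per cell (in
#'   `dev` column order).
#' @param tumor_type,ref_type cell-type labels for the two populations.
#' @param q_cut BH-adjusted cutoff (default 0.05).
#' @return tibble: `motif_id`, `n_significant`, `n_compared`, `direction`,
#'   `pass_half`, `pass_all`.
#' @export
differential_motifs <- function(dev, cell_meta, tumor_type = "Tumor",
                                ref_type = "PT", q_cut = 0.05) {
  ref <- which(cell_meta$cell_type == ref_type)
  if (length(ref) < 3) abort("too few reference cells", class = "nephromics_stat_error")
  samples <- unique(cell_meta$sample_id[cell_meta$cell_type == tumor_type])
  res_p <- res_d <- matrix(NA_real_, nrow(dev), length(samples),
                           dimnames = list(rownames(dev), samples))
  for (s in samples) {
    tum <- which(cell_meta$sample_id == s & cell_meta$cell_type == tumor_type)
    if (length(tum) < 3) next
    sub <- dev[, c(tum, ref), drop = FALSE]
    p <- rank_sum_rows(sub, seq_along(tum))
    res_p[, s] <- adjust_p(p, "BH")
    res_d[, s] <- sign(rowMeans(dev[, tum, drop = FALSE]) -
                         rowMeans(dev[, ref, drop = FALSE]))
  }
  n_cmp <- rowSums(!is.na(res_p))
  sig <- !is.na(res_p) & res_p < q_cut
  res <- purrr::map_dfr(rownames(dev), function(m) {
    s <- sig[m, ] & !is.na(res_d[m, ])
    dirs <- res_d[m, s]
    coherent <- length(dirs) > 0 && length(unique(dirs)) == 1 && all(dirs != 0)
    tibble(
      motif_id = m,
      n_significant = sum(s),
      n_compared = n_cmp[m],
      direction = if (coherent) dirs[1] else 0,
      pass_half = coherent && n_cmp[m] > 0 && sum(s) / n_cmp[m] >= 0.5,
      pass_all = coherent && n_cmp[m] > 0 && sum(s) == n_cmp[m]
    )
  })
  res
}
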