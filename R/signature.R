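#' @importFrom survival Surv survfit survdiff
NULL

#' Build the tumor-cell-intrinsic signature
#'
#' Identifies the tumor subclusters in the top and bottom deciles of a
#' per-cluster score (e.g. inflammatory response), runs DE between the cells
#' of the two cluster groups, keeps genes significantly up in the top group,
#' and intersects them with the tumor-cell-specific marker list — yielding a
#' signature attributable to tumor cells rather than infiltrating immune
#' cells when scored on bulk data.
#'
#' @param norm [norm_matrix()] with `cluster_id` cell metadata.
#' @param cluster_scores named numeric vector: score per tumor cluster.
#' @param markers character vector of tumor-cell-specific markers.
#' @param top_q,bottom_q score quantiles defining the two cluster groups
#'   (defaults 0.9 / 0.1; strictly above / below the interpolated quantile,
#'   so 10 distinct-scored clusters give one cluster per tail).
#' @param p_cut adjusted p cutoff for the DE step.
#' @return character vector of signature genes (with attribute `de` holding
#'   the DE table); empty with a warning when the intersection is empty.
#' @export
build_intrinsic_signature <- function(norm, cluster_scores, markers,
                                      top_q = 0.9, bottom_q = 0.1,
                                      p_cut = 0.05) {
  qs <- quantile(cluster_scores, c(bottom_q, top_q), type = 7)
  top <- names(cluster_scores)[cluster_scores > qs[2]]
  bottom <- names(cluster_scores)[cluster_scores < qs[1]]
  if (!length(top) || !length(bottom)) {
    abort("score quantiles leave an empty cluster group", class = "nephromics_stat_error")
  }
  meta <- norm$cell_meta
  de <- wilcoxon_de(norm, which(meta$cluster_id %in% top),
                    which(meta$cluster_id %in% bottom),
                    min_pct = 0.1, min_diff_pct = 0)
  up <- de$gene[!is.na(de$p_adj) & de$p_adj < p_cut & de$lfc > 0]
  sig <- intersect(up, markers)
  if (!length(sig)) warn("signature is empty: no overlap between DEGs and markers")
  attr(sig, "de") <- de
  sig
}

#' Score bulk samples with a gene signature
#'
#' Each signature gene's log2 FPKM vector is z-scaled across samples; a
#' sample's score is the mean scaled expression over the signature genes
#' (invariant to adding a constant to any gene's row).
#'
#' @param bulk [bulk_cohort()] or a genes-by-samples matrix.
#' @param genes signature gene ids.
#' @return tibble with `sample_id` and `score`.
#' @export
bulk_signature_score <- function(bulk, genes) {
  expr <- if (inherits(bulk, "bulk_cohort")) bulk$expr else as.matrix(bulk)
  genes <- intersect(genes, rownames(expr))
  if (!length(genes)) abort("no signature genes in the expression matrix",
                            class = "nephromics_stat_error")
  z <- scale_rows(expr[genes, , drop = FALSE], context = "signature score")
  tibble(sample_id = colnames(expr), score = unname(colMeans(z)))
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator with conventional censoring handling (thin wrapper
#' over [survival::survfit()]).
#'
#' @param times follow-up times.
#' @param events event indicators (1 = event, 0 = censored).
#' @return tibble with `time`, `n_risk`, `n_event`, `surv`.
#' @export
km_estimate <- function(times, events) {
  fit <- survfit(Surv(times, events) ~ 1)
  tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
         surv = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected chi-square statistic on one degree of
#' freedom; identical groups give statistic 0 and p = 1, and the result is
#' invariant to label swapping.
#'
#' @param times,events follow-up times and event indicators.
#' @param group two-level group labels.
#' @return list with `statistic` and `p`.
#' @export
logrank_test <- function(times, events, group) {
  if (length(unique(group)) != 2) abort("log-rank needs exactly two groups",
                                        class = "nephromics_stat_error")
  sd <- survdiff(Surv(times, events) ~ group)
  stat <- sd$chisq
  list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Quantile-stratified Kaplan-Meier comparison
#'
#' Splits samples into a low group (the `ceiling(n * lo_q)` lowest values)
#' and a high group (the `ceiling(n * (1 - hi_q))` highest), discards the
#' middle, and compares the groups with a two-sided log-rank test. Ordering
#' ties are broken by sample id, so group membership is deterministic. The
#' default 25%/75% split reproduces 26-per-tail groups for a 103-sample
#' cohort.
#'
#' @param scores tibble with `sample_id` and `score` (e.g. from
#'   [bulk_signature_score()]) or a named numeric vector.
#' @param clinical tibble with `sample_id`, `surv_time`, `event`; rows with
#'   missing survival are dropped.
#' @param lo_q,hi_q quantile bounds (defaults 0.25 and 0.75; the marker-level
#'   analysis uses 0.30/0.70).
#' @return object of class `surv_strat`: list with `groups` (tibble),
#'   `km` (per-group KM tibble), `statistic`, `p`, `fit` (survfit object).
#' @export
quantile_stratified_survival <- function(scores, clinical, lo_q = 0.25,
                                         hi_q = 0.75) {
  if (!is.data.frame(scores)) {
    scores <- tibble(sample_id = names(scores), score = as.numeric(scores))
  }
  d <- dplyr::inner_join(scores, clinical, by = "sample_id") |>
    dplyr::filter(!is.na(.data$surv_time), !is.na(.data$event)) |>
    dplyr::arrange(.data$score, .data$sample_id)
  n <- nrow(d)
  if (n < 4) abort("too few samples with survival data", class = "nephromics_stat_error")
  k_lo <- ceiling(round(n * lo_q, 9))
  k_hi <- ceiling(round(n * (1 - hi_q), 9))
  if (k_lo + k_hi > n) abort("quantile groups overlap", class = "nephromics_config_error")
  d$group <- NA_character_
  d$group[seq_len(k_lo)] <- "low"
  d$group[(n - k_hi + 1):n] <- "high"
  d <- d[!is.na(d$group), ]
  lr <- logrank_test(d$surv_time, d$event, d$group)
  fit <- survfit(Surv(surv_time, event) ~ group, data = d)
  km <- dplyr::bind_rows(lapply(c("high", "low"), function(g) {
    sub <- d[d$group == g, ]
    dplyr::mutate(km_estimate(sub$surv_time, sub$event), group = g)
  }))
  structure(list(groups = tibble(sample_id = d$sample_id, score = d$score,
                                 group = d$group),
                 km = km, statistic = lr$statistic, p = lr$p, fit = fit),
            class = "surv_strat")
}

#' @export
print.surv_strat <- function(x, ...) {
  n <- table(x$groups$group)
  cat(sprintf("<surv_strat> high n=%d vs low n=%d; log-rank chi-sq = %.3f, p = %.3g\n",
              n[["high"]], n[["low"]], x$statistic, x$p))
  invisible(x)
}
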