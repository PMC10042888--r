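#' Call copy gain/loss per segment
#'
#' A segment is a copy gain when its log2 copy ratio is strictly greater
#' than `gain` and a loss when strictly smaller than `loss`; otherwise
#' neutral (the boundary values are neutral).
#'
#' @param segments segment tibble (see [segment_table()]).
#' @param gain,loss thresholds (defaults +0.2 / -0.2).
#' @return the segment tibble with a `call` column (`gain`/`loss`/`neutral`).
#' @export
call_segments <- function(segments, gain = 0.2, loss = -0.2) {
  segments <- segment_table(segments)
  segments$call <- ifelse(segments$log2cr > gain, "gain",
                          ifelse(segments$log2cr < loss, "loss", "neutral"))
  segments
}

#' Length-weighted arm-level copy-number summarization
#'
#' Per sample and chromosome arm, sums the segment-level log2 copy ratios
#' weighted by segment length: `sum(len_i * log2cr_i) / sum(len_i)` over the
#' segments in the arm (segments are half-open, so `len = end - start`).
#' Splitting a segment into contiguous equal-ratio pieces leaves the result
#' unchanged. The arm value is called gain/loss with the same thresholds as
#' segments. Segments without an `arm` label are assigned by midpoint overlap
#' with `arm_map`.
#'
#' @param segments segment tibble.
#' @param arm_map tibble (`chrom`, `arm`, `start`, `end`) used when segment
#'   arm labels are missing; defaults to [toy_arm_map()].
#' @param gain,loss call thresholds.
#' @return tibble of class `arm_calls`: `sample_id`, `arm`,
#'   `weighted_log2cr`, `call`.
#' @export
arm_weighted <- function(segments, arm_map = NULL, gain = 0.2, loss = -0.2) {
  segments <- segment_table(segments)
  if (anyNA(segments$arm)) {
    arm_map <- arm_map %||% toy_arm_map()
    mid <- (segments$start + segments$end) / 2
    fill <- is.na(segments$arm)
    segments$arm[fill] <- vapply(which(fill), function(i) {
      hit <- arm_map$chrom == segments$chrom[i] &
        arm_map$start <= mid[i] & mid[i] < arm_map$end
      if (!any(hit)) NA_character_ else arm_map$arm[which(hit)[1]]
    }, character(1))
  }
  out <- segments |>
    dplyr::filter(!is.na(.data$arm)) |>
    dplyr::group_by(.data$sample_id, .data$arm) |>
    dplyr::summarise(
      weighted_log2cr = sum((.data$end - .data$start) * .data$log2cr) /
        sum(.data$end - .data$start),
      .groups = "drop"
    ) |>
    dplyr::mutate(call = ifelse(.data$weighted_log2cr > gain, "gain",
                                ifelse(.data$weighted_log2cr < loss, "loss",
                                       "neutral")))
  class(out) <- c("arm_calls", class(out))
  out
}

#' Association of cluster copy-number status with pathway scores
#'
#' Point-biserial Pearson correlation between a binary per-cluster CNV
#' status (e.g. gain vs no-gain at a locus) and a per-cluster score, with a
#' two-sided t-based p-value and BH correction across loci; a rank-sum
#' p-value is reported alongside as a robustness column. Constant status
#' vectors yield `NA` with a warning.
#'
#' @param status named 0/1 vector (single locus) or loci-by-clusters 0/1
#'   matrix of CNV status.
#' @param scores named numeric vector of cluster scores.
#' @return tibble: `locus`, `n`, `r`, `p`, `p_wilcox`, `p_adj`.
#' @export
cnv_score_association <- function(status, scores) {
  if (is.null(dim(status))) status <- matrix(status, nrow = 1,
                                             dimnames = list("locus", names(status)))
  clusters <- intersect(colnames(status), names(scores))
  if (length(clusters) < 3) abort("need >= 3 clusters in common",
                                  class = "nephromics_stat_error")
  rows <- purrr::map_dfr(rownames(status), function(lo) {
    x <- as.numeric(status[lo, clusters])
    y <- as.numeric(scores[clusters])
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    if (length(unique(x)) < 2 || stats::sd(y) == 0) {
      warn(sprintf("locus '%s': constant status or scores; association undefined", lo))
      return(tibble(locus = lo, n = length(x), r = NA_real_, p = NA_real_,
                    p_wilcox = NA_real_))
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    pw <- suppressWarnings(wilcox.test(y[x == 1], y[x == 0], exact = FALSE)$p.value)
    tibble(locus = lo, n = length(x), r = unname(ct$estimate), p = ct$p.value,
           p_wilcox = pw)
  })
  rows$p_adj <- adjust_p(rows$p, "BH")
  rows
}
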