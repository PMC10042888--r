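#' @import ggplot2
NULL

#' Kaplan-Meier plot for a stratified survival fit
#'
#' @param object `surv_strat` object.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.surv_strat <- function(object, ...) {
  km <- tidy(object)
  km0 <- dplyr::bind_rows(
    tibble(group = unique(km$group), time = 0, surv = 1),
    km[, c("group", "time", "surv")]
  )
  ggplot(km0, aes(x = .data$time, y = .data$surv, color = .data$group)) +
    geom_step() +
    coord_cartesian(ylim = c(0, 1)) +
    labs(x = "Time", y = "Survival probability", color = "Score group",
         subtitle = sprintf("log-rank p = %.3g", object$p)) +
    theme_minimal()
}

#' Volcano plot for a differential expression result
#'
#' @param object `de_result` tibble.
#' @param p_cut,lfc_cut highlighting thresholds.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.de_result <- function(object, p_cut = 0.05, lfc_cut = 0, ...) {
  d <- object[!is.na(object$p_adj), ]
  d$state <- ifelse(d$p_adj < p_cut & d$lfc > lfc_cut, "up",
                    ifelse(d$p_adj < p_cut & d$lfc < -lfc_cut, "down", "ns"))
  ggplot(d, aes(x = .data$lfc, y = -log10(pmax(.data$p_adj, 1e-300)),
                color = .data$state)) +
    geom_point(size = 0.6, alpha = 0.7) +
    scale_color_manual(values = c(up = "#c0392b", down = "#2980b9", ns = "grey70")) +
    labs(x = "log2 fold change", y = "-log10 adjusted p", color = NULL) +
    theme_minimal()
}

#' Heatmap of pathway scores across tumor subclusters
#'
#' @param object `score_matrix` object.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.score_matrix <- function(object, ...) {
  long <- tidy(object)
  ggplot(long, aes(x = .data$cluster_id, y = .data$set, fill = .data$score)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b") +
    labs(x = "Tumor subcluster", y = NULL, fill = "Score") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5, hjust = 1, size = 6))
}

#' Arm-level copy-number profile plot
#'
#' @param object `arm_calls` tibble from [arm_weighted()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.arm_calls <- function(object, ...) {
  ggplot(object, aes(x = .data$arm, y = .data$sample_id,
                     fill = .data$weighted_log2cr)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                         limits = c(-1, 1), oob = scales_squish) +
    labs(x = "Chromosome arm", y = "Sample", fill = "log2 CR") +
    theme_minimal()
}

# minimal squish to avoid a scales dependency at runtime
scales_squish <- function(x, range = c(0, 1), only.finite = TRUE) {
  pmin(pmax(x, range[1]), range[2])
}
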