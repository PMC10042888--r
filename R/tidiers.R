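#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a quantile-stratified survival fit
#'
#' One row per event time per group with the Kaplan-Meier estimate.
#'
#' @param x `surv_strat` object.
#' @param ... unused.
#' @return tibble with `group`, `time`, `n_risk`, `n_event`, `surv`.
#' @export
tidy.surv_strat <- function(x, ...) {
  as_tibble(x$km[, c("group", "time", "n_risk", "n_event", "surv")])
}

#' One-row summary of a quantile-stratified survival fit
#'
#' @param x `surv_strat` object.
#' @param ... unused.
#' @return tibble with group sizes, log-rank statistic and p-value.
#' @export
glance.surv_strat <- function(x, ...) {
  n <- table(x$groups$group)
  tibble(n_high = as.integer(n[["high"]]), n_low = as.integer(n[["low"]]),
         statistic = x$statistic, p.value = x$p)
}

#' Tidy a pathway score matrix into long form
#'
#' @param x `score_matrix` object.
#' @param ... unused.
#' @return tibble with `cluster_id`, `set`, `score` (plus cluster metadata
#'   when present).
#' @export
tidy.score_matrix <- function(x, ...) {
  long <- as_tibble(x$scores, rownames = "cluster_id") |>
    tidyr::pivot_longer(-"cluster_id", names_to = "set", values_to = "score")
  if (!is.null(x$cluster_meta)) {
    long <- dplyr::left_join(long, x$cluster_meta, by = "cluster_id")
  }
  long
}

#' One-row summary of a DACR consensus result
#'
#' @param x `dacr_result` tibble.
#' @param ... unused.
#' @return tibble with peak counts by outcome and direction.
#' @export
glance.dacr_result <- function(x, ...) {
  tibble(
    n_peaks = nrow(x),
    n_pass = sum(x$final_pass),
    n_up = sum(x$final_pass & x$direction > 0),
    n_down = sum(x$final_pass & x$direction < 0),
    pct_down = if (sum(x$final_pass)) 100 * sum(x$final_pass & x$direction < 0) /
      sum(x$final_pass) else NA_real_
  )
}
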