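#' @importFrom stats pnorm pchisq phyper p.adjust quantile rnbinom rnorm runif
#'   rbinom rexp rlnorm plogis glm.fit binomial wilcox.test cor complete.cases
NULL

#' Depth-normalize a count matrix
#'
#' Divides each cell's counts by the cell total, multiplies by `scale_factor`,
#' and log-transforms: `value = ln(1 + count * scale_factor / total)`. Zero
#' counts map to exactly zero.
#'
#' @param x [sn_counts()] object (or a bare matrix).
#' @param scale_factor positive scale factor (default 10,000).
#' @return [norm_matrix()] object (or a sparse matrix if `x` was bare).
#' @export
lognormalize <- function(x, scale_factor = 1e4) {
  bare <- !inherits(x, "sn_counts")
  m <- if (bare) as(as(x, "CsparseMatrix"), "generalMatrix") else x$counts
  totals <- Matrix::colSums(m)
  if (any(totals == 0)) {
    bad <- colnames(m)[which(totals == 0)[1]]
    abort(sprintf("cell '%s' has zero total counts", bad %||% "<unnamed>"),
          class = "nephromics_stat_error")
  }
  v <- m
  v@x <- log1p(v@x * rep.int(scale_factor / totals, diff(v@p)))
  if (bare) return(v)
  norm_matrix(v, x$gene_ids, x$cell_ids, x$cell_meta, scale_factor = scale_factor)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Average de-logged expression by cell group
#'
#' For each group, the mean over its cells of `expm1(value)` — i.e. average
#' expression on the de-logged (linear) scale, matching non-log dot plots.
#'
#' @param norm [norm_matrix()] object.
#' @param grouping either a vector of group labels per cell or the name of a
#'   `cell_meta` column (or character vector of columns, combined with `"_"`).
#' @return genes-by-groups dense matrix.
#' @export
group_mean_expression <- function(norm, grouping = "cell_type") {
  g <- resolve_grouping(norm, grouping)
  v <- norm$values
  v@x <- expm1(v@x)
  groups <- sort(unique(g))
  ind <- Matrix::sparseMatrix(
    i = seq_along(g), j = match(g, groups), x = 1,
    dims = c(length(g), length(groups))
  )
  sizes <- as.numeric(Matrix::colSums(ind))
  out <- as.matrix(v %*% ind) / rep(sizes, each = nrow(v))
  dimnames(out) <- list(norm$gene_ids, groups)
  out
}

resolve_grouping <- function(x, grouping) {
  if (length(grouping) == length(x$cell_ids) && !all(grouping %in% names(x$cell_meta))) {
    return(as.character(grouping))
  }
  cols <- lapply(grouping, function(col) {
    if (!col %in% names(x$cell_meta)) {
      abort(sprintf("no cell_meta column '%s'", col), class = "nephromics_config_error")
    }
    x$cell_meta[[col]]
  })
  if (length(cols) == 1) as.character(cols[[1]]) else do.call(paste, c(cols, sep = "_"))
}

# Row-wise two-sided Mann-Whitney rank-sum test. Small untied samples
# (N <= 30) use the exact null distribution; otherwise the normal
# approximation with tie and continuity correction. X is dense genes x
# cells; idx_a indexes group-A columns. Returns p-values.
rank_sum_rows <- function(X, idx_a, exact_max_n = 30) {
  n <- ncol(X)
  n_a <- length(idx_a)
  n_b <- n - n_a
  mu <- n_a * n_b / 2
  apply(X, 1L, function(v) {
    r <- rank(v)
    U <- sum(r[idx_a]) - n_a * (n_a + 1) / 2
    t <- rle(sort(v))$lengths
    if (n <= exact_max_n && length(t) == n) {
      p <- if (U > mu) {
        stats::pwilcox(U - 1, n_a, n_b, lower.tail = FALSE)
      } else {
        stats::pwilcox(U, n_a, n_b)
      }
      return(min(1, 2 * p))
    }
    sig2 <- (n_a * n_b / 12) * ((n + 1) - sum(t^3 - t) / (n * (n - 1)))
    if (sig2 <= 0) return(1)
    d <- U - mu
    z <- (d - sign(d) * 0.5) / sqrt(sig2)
    min(1, 2 * pnorm(-abs(z)))
  })
}

#' Rank-sum differential expression between two cell groups
#'
#' Two-sided Wilcoxon rank-sum test (normal approximation with tie and
#' continuity correction) on log-normalized values, with the single-cell
#' pre-filters on detection fractions and fold change. The fold change is
#' `log2((mean_A + 1) / (mean_B + 1))` on de-logged group means. The
#' Bonferroni denominator is the total number of genes in the matrix
#' (pre-filter), so adjusted p-values are comparable across filtered runs.
#'
#' @param norm [norm_matrix()] object.
#' @param cells_a,cells_b character cell ids or integer/logical column indices
#'   of the two groups (each with at least 3 cells).
#' @param min_pct test only genes detected in at least this fraction of cells
#'   in either group (default 0.1).
#' @param min_diff_pct minimum absolute difference in detection fractions
#'   (default 0).
#' @param lfc_threshold minimum absolute log2 fold change (default 0).
#' @return tibble of class `de_result` with columns `gene`, `lfc`, `pct1`,
#'   `pct2`, `p`, `p_adj`, `direction`, `filtered_reason` (`NA` for tested
#'   genes; filtered genes have `NA` p-values).
#' @export
wilcoxon_de <- function(norm, cells_a, cells_b, min_pct = 0.1,
                        min_diff_pct = 0, lfc_threshold = 0) {
  ia <- resolve_cells(norm, cells_a)
  ib <- resolve_cells(norm, cells_b)
  if (length(ia) < 3 || length(ib) < 3) {
    abort("each group needs at least 3 cells", class = "nephromics_stat_error")
  }
  v <- norm$values
  va <- v[, ia, drop = FALSE]
  vb <- v[, ib, drop = FALSE]
  pct1 <- Matrix::rowSums(va > 0) / length(ia)
  pct2 <- Matrix::rowSums(vb > 0) / length(ib)
  mean_a <- Matrix::rowSums(expm1_sp(va)) / length(ia)
  mean_b <- Matrix::rowSums(expm1_sp(vb)) / length(ib)
  lfc <- log2((mean_a + 1) / (mean_b + 1))
  reason <- rep(NA_character_, nrow(v))
  reason[pmax(pct1, pct2) < min_pct] <- "min_pct"
  reason[is.na(reason) & abs(pct1 - pct2) < min_diff_pct] <- "min_diff_pct"
  reason[is.na(reason) & abs(lfc) < lfc_threshold] <- "lfc_threshold"
  keep <- which(is.na(reason))
  p <- rep(NA_real_, nrow(v))
  if (length(keep)) {
    X <- as.matrix(cbind(va[keep, , drop = FALSE], vb[keep, , drop = FALSE]))
    p[keep] <- rank_sum_rows(X, seq_along(ia))
  }
  m <- nrow(v)  # Bonferroni over all genes in the matrix
  out <- tibble(
    gene = norm$gene_ids, lfc = lfc, pct1 = pct1, pct2 = pct2,
    p = p, p_adj = pmin(1, p * m), direction = sign(lfc),
    filtered_reason = reason
  )
  class(out) <- c("de_result", class(out))
  out
}

expm1_sp <- function(m) { m@x <- expm1(m@x); m }

resolve_cells <- function(x, cells) {
  ids <- x$cell_ids
  if (is.character(cells)) {
    idx <- match(cells, ids)
    if (anyNA(idx)) abort("unknown cell ids", class = "nephromics_config_error")
    idx
  } else if (is.logical(cells)) {
    which(cells)
  } else {
    as.integer(cells)
  }
}

#' Likelihood-ratio logistic test with latent covariates
#'
#' For each feature, compares the logistic models
#' `group ~ feature + covariates` vs `group ~ covariates` with a chi-square
#' likelihood-ratio test (df = 1). A covariate that fully explains the feature
#' drives its p-value toward 1 — this is the mechanism used for copy-number
#' correction. Perfect separation is detected and refitted with Firth
#' penalized likelihood; such features are flagged.
#'
#' @param features numeric matrix (features x observations) or a single
#'   numeric vector.
#' @param group binary group labels (logical, 0/1, or two-level factor).
#' @param covariates optional numeric matrix (observations x k) of latent
#'   covariates, e.g. per-cell FRiP and CNV values.
#' @return tibble with columns `feature`, `p`, `stat`, `separation`.
#' @export
lr_group_test <- function(features, group, covariates = NULL) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  y <- as.numeric(as.factor(group)) - 1
  if (!all(y %in% c(0, 1))) abort("group must be binary", class = "nephromics_stat_error")
  n <- length(y)
  if (ncol(features) != n) abort("features/group length mismatch", class = "nephromics_stat_error")
  X0 <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (any(!is.finite(covariates))) abort("non-finite covariates", class = "nephromics_stat_error")
    X0 <- cbind(X0, covariates)
  }
  fit0 <- suppressWarnings(glm.fit(X0, y, family = binomial()))
  dev0 <- fit0$deviance
  res <- lapply(seq_len(nrow(features)), function(i) {
    f <- features[i, ]
    X1 <- cbind(X0, feature = f)
    fit1 <- suppressWarnings(glm.fit(X1, y, family = binomial()))
    stat <- max(0, dev0 - fit1$deviance)
    beta <- fit1$coefficients[["feature"]]
    sep <- isTRUE(!is.na(beta) && abs(beta) > 12) ||
      (fit1$converged == FALSE) ||
      any(fit1$fitted.values > 1 - 1e-9) || any(fit1$fitted.values < 1e-9)
    if (sep) {
      pl1 <- firth_loglik(X1, y)
      pl0 <- firth_loglik(X0, y)
      stat <- max(0, 2 * (pl1 - pl0))
    }
    c(stat = stat, sep = as.numeric(sep))
  })
  stat <- vapply(res, `[[`, numeric(1), "stat")
  sep <- vapply(res, `[[`, numeric(1), "sep") > 0
  tibble(
    feature = rownames(features) %||% as.character(seq_len(nrow(features))),
    p = pchisq(stat, df = 1, lower.tail = FALSE),
    stat = stat,
    separation = sep
  )
}

# Firth-penalized logistic log-likelihood at the penalized MLE.
firth_loglik <- function(X, y, maxit = 60, tol = 1e-7) {
  qrX <- qr(X)
  X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    W <- pmax(p * (1 - p), 1e-12)
    XW <- X * sqrt(W)
    I <- crossprod(XW)
    Iinv <- tryCatch(solve(I), error = function(e) MASS_ginv(I))
    h <- rowSums((XW %*% Iinv) * XW)
    U <- drop(crossprod(X, y - p + h * (0.5 - p)))
    delta <- drop(Iinv %*% U)
    delta <- delta * min(1, 5 / max(abs(delta)))  # step damping
    beta <- beta + delta
    if (max(abs(delta)) < tol) break
  }
  eta <- drop(X %*% beta)
  p <- plogis(eta)
  W <- pmax(p * (1 - p), 1e-12)
  ll <- sum(y * log(pmax(p, 1e-300)) + (1 - y) * log(pmax(1 - p, 1e-300)))
  ll + 0.5 * as.numeric(determinant(crossprod(X * sqrt(W)))$modulus)
}

MASS_ginv <- function(m) {
  s <- svd(m)
  pos <- s$d > max(1e-12 * s$d[1], 0)
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Multiple-testing adjustment
#'
#' Thin wrapper over [stats::p.adjust()] restricted to the two corrections
#' used in the pipeline; `m` lets the Bonferroni/BH denominator be the full
#' feature universe rather than the tested subset.
#'
#' @param p numeric p-values (`NA`s preserved).
#' @param method `"bonferroni"` or `"BH"`.
#' @param m number of comparisons (defaults to `length(p)`).
#' @return adjusted p-values.
#' @export
adjust_p <- function(p, method = c("bonferroni", "BH"), m = length(p)) {
  method <- match.arg(method)
  p.adjust(p, method = method, n = max(m, sum(!is.na(p))))
}

#' One-sided over-representation test
#'
#' Hypergeometric upper-tail (one-sided Fisher) test of a query gene list
#' against each gene set, restricted to a stated background universe, with BH
#' correction across sets.
#'
#' @param query character vector of query genes (must be a subset of
#'   `background`).
#' @param sets [gene_sets()] collection (or a single character vector).
#' @param background character vector defining the gene universe.
#' @return tibble with columns `set`, `overlap`, `n_query`, `n_set`, `n_bg`,
#'   `odds`, `p`, `p_adj`.
#' @export
overrep_test <- function(query, sets, background) {
  if (!is.list(sets)) sets <- gene_sets(list(set = sets))
  query <- unique(query)
  background <- unique(background)
  if (!all(query %in% background)) {
    abort("query genes must be contained in the background", class = "nephromics_stat_error")
  }
  N <- length(background)
  n_q <- length(query)
  rows <- purrr::map_dfr(names(sets), function(nm) {
    set_bg <- intersect(sets[[nm]], background)
    K <- length(set_bg)
    a <- length(intersect(query, set_bg))
    p <- if (K == 0) 1 else phyper(a - 1, K, N - K, n_q, lower.tail = FALSE)
    b <- n_q - a
    cc <- K - a
    d <- N - n_q - cc
    tibble(set = nm, overlap = a, n_query = n_q, n_set = K, n_bg = N,
           odds = (a * d) / max(b * cc, .Machine$double.eps), p = p)
  })
  rows$p_adj <- adjust_p(rows$p, "BH")
  rows
}
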