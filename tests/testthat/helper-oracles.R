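# Independent brute-force oracles used to check the fast implementations.

# Exact two-sided Mann-Whitney p by enumerating all group-A assignments.
perm_rank_sum_p <- function(a, b) {
  v <- c(a, b)
  n_a <- length(a)
  r <- rank(v)
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  mu <- n_a * length(b) / 2
  combos <- utils::combn(length(v), n_a)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - n_a * (n_a + 1) / 2)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Hypergeometric upper tail by direct summation.
hyper_tail_p <- function(overlap, n_set, n_query, n_bg) {
  ks <- overlap:min(n_set, n_query)
  sum(choose(n_set, ks) * choose(n_bg - n_set, n_query - ks)) /
    choose(n_bg, n_query)
}

# Kaplan-Meier by hand: product over event times.
manual_km <- function(times, events) {
  ord <- order(times)
  times <- times[ord]; events <- events[ord]
  ut <- unique(times[events == 1])
  s <- 1
  out <- numeric(0)
  for (t in ut) {
    n_risk <- sum(times >= t)
    d <- sum(times == t & events == 1)
    s <- s * (1 - d / n_risk)
    out <- c(out, s)
  }
  tibble::tibble(time = ut, surv = out)
}

# Greedy peak retention by descending score, removing overlaps, O(n^2).
brute_dedup <- function(peaks) {
  ord <- order(-peaks$score, peaks$chrom, peaks$start, peaks$peak_id)
  kept <- list()
  for (i in ord) {
    ov <- FALSE
    for (j in seq_along(kept)) {
      k <- kept[[j]]
      if (peaks$chrom[i] == k$chrom && peaks$start[i] < k$end &&
          k$start < peaks$end[i]) { ov <- TRUE; break }
    }
    if (!ov) kept[[length(kept) + 1]] <- peaks[i, ]
  }
  dplyr::bind_rows(kept) |> dplyr::arrange(.data$chrom, .data$start)
}

# Gene activity by direct interval overlap counting.
brute_gene_activity <- function(pm, genes, upstream = 2000) {
  out <- matrix(0, nrow(genes), ncol(pm$counts),
                dimnames = list(genes$gene_id, pm$cell_ids))
  for (g in seq_len(nrow(genes))) {
    ws <- if (genes$strand[g] == "+") genes$start[g] - upstream else genes$start[g]
    we <- if (genes$strand[g] == "+") genes$end[g] else genes$end[g] + upstream
    for (p in seq_len(nrow(pm$peaks))) {
      ps <- pm$peaks$start[p] + 1  # 1-based inclusive
      pe <- pm$peaks$end[p]
      if (pm$peaks$chrom[p] == genes$chrom[g] && ps <= we && ws <= pe) {
        out[g, ] <- out[g, ] + as.numeric(pm$counts[p, ])
      }
    }
  }
  out
}

# All-window PWM scores on both strands by direct summation.
brute_scan <- function(p, seq, threshold) {
  bases <- c("A", "C", "G", "T")
  lo <- log2(p$matrix / p$background)
  lo[!is.finite(lo) | lo < -20] <- -20
  L <- ncol(lo)
  chars <- strsplit(seq, "")[[1]]
  code <- match(chars, bases)
  rc <- c(4, 3, 2, 1)
  hits <- list()
  for (off in seq_len(length(code) - L + 1)) {
    win <- code[off:(off + L - 1)]
    if (anyNA(win)) next
    s_f <- sum(lo[cbind(win, seq_len(L))])
    s_r <- sum(lo[cbind(rc[rev(win)], seq_len(L))])
    if (s_f >= threshold) {
      hits[[length(hits) + 1]] <- tibble::tibble(offset = off - 1L, strand = "+",
                                                 score = s_f)
    }
    if (s_r >= threshold) {
      hits[[length(hits) + 1]] <- tibble::tibble(offset = off - 1L, strand = "-",
                                                 score = s_r)
    }
  }
  dplyr::bind_rows(hits)
}

# Exact PWM score tail by enumerating all 4^L windows.
enum_score_threshold <- function(p, p_threshold = 5e-5) {
  lo <- log2(p$matrix / p$background)
  lo[!is.finite(lo) | lo < -20] <- -20
  L <- ncol(lo)
  grid <- expand.grid(rep(list(1:4), L))
  scores <- numeric(nrow(grid))
  probs <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    w <- as.integer(grid[i, ])
    scores[i] <- sum(lo[cbind(w, seq_len(L))])
    probs[i] <- prod(p$background[w])
  }
  ord <- order(scores)
  scores <- scores[ord]; probs <- probs[ord]
  tail_p <- rev(cumsum(rev(probs)))
  ok <- which(tail_p <= p_threshold)
  if (!length(ok)) Inf else scores[min(ok)]
}
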