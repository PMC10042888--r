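test_that("lognormalize matches closed-form arithmetic and conserves totals", {
  # one cell, counts [1,1,2], scale = total = 4 -> ln2, ln2, ln3
  x <- sn_counts(matrix(c(1, 1, 2), 3, 1), c("a", "b", "c"), "c1",
                 tibble::tibble(sample_id = "S"))
  v <- lognormalize(x, scale_factor = 4)$values
  expect_equal(as.numeric(v), c(log(2), log(2), log(3)))

  # zero counts stay exactly zero
  x2 <- sn_counts(matrix(c(0, 3, 1, 0), 2, 2), c("a", "b"), c("c1", "c2"),
                  tibble::tibble(sample_id = c("S", "S")))
  v2 <- lognormalize(x2)$values
  expect_identical(as.numeric(v2 == 0), as.numeric(x2$counts == 0))

  # conservation: sum(expm1(values)) * total / scale = total per cell
  withr::with_seed(5, m <- matrix(rpois(300, 2), 30, 10))
  m[, 1][m[, 1] == 0] <- 1
  xn <- lognormalize(m, scale_factor = 123)
  totals <- Matrix::colSums(m)
  recon <- Matrix::colSums(expm1(xn)) * totals / 123
  expect_equal(as.numeric(recon), as.numeric(totals), tolerance = 1e-9)

  # all-zero cell errors, naming the cell
  bad <- sn_counts(matrix(c(1, 0), 1, 2), "g", c("ok", "empty"),
                   tibble::tibble(sample_id = c("S", "S")))
  expect_error(lognormalize(bad), "empty", class = "nephromics_stat_error")
})

test_that("group means equal a brute-force loop on de-logged values", {
  withr::with_seed(8, cnt <- matrix(rpois(200, 3), 20, 10))
  cnt[, colSums(cnt) == 0] <- 1
  grp <- rep(c("x", "y"), 5)
  norm <- tiny_norm(cnt, cell_types = grp)
  gm <- group_mean_expression(norm, grp)
  v <- as.matrix(norm$values)
  manual <- sapply(c("x", "y"), function(g) rowMeans(expm1(v[, grp == g])))
  expect_equal(unname(gm), unname(manual), tolerance = 1e-12)

  # one cell per group -> identity; equal groups -> equal columns
  norm1 <- tiny_norm(cnt[, 1:2, drop = FALSE], cell_types = c("a", "b"))
  gm1 <- group_mean_expression(norm1, c("a", "b"))
  expect_equal(unname(gm1), unname(expm1(as.matrix(norm1$values))))
  normd <- tiny_norm(cbind(cnt[, 1], cnt[, 1]), cell_types = c("a", "b"))
  gmd <- group_mean_expression(normd, c("a", "b"))
  expect_equal(gmd[, 1], gmd[, 2])
})

test_that("rank-sum DE agrees with exact permutation enumeration at n=8+8", {
  withr::with_seed(11, {
    cnt <- matrix(rpois(30 * 16, 4) + 1, 30, 16)  # +1: no all-zero cells
    vals <- matrix(rnorm(30 * 16), 30, 16)        # continuous, no ties
  })
  norm <- tiny_norm(cnt)
  norm$values <- as(as(exp(abs(vals)), "CsparseMatrix"), "generalMatrix")
  dimnames(norm$values) <- list(norm$gene_ids, norm$cell_ids)
  de <- wilcoxon_de(norm, 1:8, 9:16, min_pct = 0, min_diff_pct = 0)
  for (i in seq_len(30)) {
    p_exact <- perm_rank_sum_p(as.numeric(norm$values[i, 1:8]),
                               as.numeric(norm$values[i, 9:16]))
    expect_lt(abs(de$p[i] - p_exact) / p_exact, 0.10)
  }
})

test_that("rank-sum DE obeys its symmetry and filter contracts", {
  withr::with_seed(12, cnt <- matrix(rpois(40 * 40, 2), 40, 40))
  cnt[1, ] <- 0; cnt[1, c(1, 21)] <- 1        # 5% detection in both groups
  cnt[, colSums(cnt) == 0] <- 1
  norm <- tiny_norm(cnt)
  de <- wilcoxon_de(norm, 1:20, 21:40, min_pct = 0.1, min_diff_pct = 0)
  expect_equal(de$filtered_reason[1], "min_pct")
  expect_true(is.na(de$p[1]))

  # identical groups: p = 1 everywhere
  normi <- tiny_norm(cbind(cnt[, 1:5], cnt[, 1:5]))
  dei <- wilcoxon_de(normi, 1:5, 6:10, min_pct = 0, min_diff_pct = 0)
  expect_true(all(dei$p[!is.na(dei$p)] == 1))

  # swapping groups negates lfc and preserves p exactly
  d1 <- wilcoxon_de(norm, 1:10, 11:20, min_pct = 0, min_diff_pct = 0)
  d2 <- wilcoxon_de(norm, 11:20, 1:10, min_pct = 0, min_diff_pct = 0)
  expect_equal(d1$p, d2$p)
  expect_equal(d1$lfc, -d2$lfc, tolerance = 1e-12)

  # invariance to strictly monotone transforms of the values (rank test)
  normt <- norm
  normt$values@x <- normt$values@x^1.7 + 0.3 * normt$values@x
  dt <- wilcoxon_de(normt, 1:10, 11:20, min_pct = 0, min_diff_pct = 0)
  expect_equal(dt$p, d1$p)

  # p_adj >= p and p_adj uses the full gene universe
  expect_true(all(d1$p_adj >= d1$p, na.rm = TRUE))
  expect_equal(d1$p_adj, pmin(d1$p * 40, 1))

  expect_error(wilcoxon_de(norm, 1:2, 3:20), class = "nephromics_stat_error")
})

test_that("logistic LRT with latent covariates behaves at null, separation and collinearity", {
  withr::with_seed(21, {
    y <- rbinom(200, 1, 0.5)
    feats <- matrix(rnorm(500 * 200), 500, 200)
  })
  res <- lr_group_test(feats, y)
  ks <- suppressWarnings(stats::ks.test(res$p, "punif"))
  expect_gt(ks$p.value, 0.01)      # null p-values are uniform
  expect_false(any(res$separation))

  # feature equal to the group indicator: separation flagged, p tiny
  sep <- lr_group_test(matrix(y, 1), y)
  expect_true(sep$separation[1])
  expect_lt(sep$p[1], 1e-6)

  # covariate identical to the feature absorbs it: p ~ 1 (CNV-correction semantics)
  f <- rnorm(200)
  col <- lr_group_test(matrix(f, 1), y, covariates = cbind(f))
  expect_gt(col$p[1], 0.99)

  # monotone in effect size at fixed n
  withr::with_seed(22, {
    x0 <- rnorm(200)
    ps <- vapply(c(0.2, 0.6, 1.2), function(b) {
      yy <- rbinom(200, 1, plogis(b * x0))
      lr_group_test(matrix(x0, 1), yy)$p
    }, numeric(1))
  })
  expect_true(all(diff(ps) < 0))
})

test_that("p-value adjustment matches hand-computed vectors and orderings", {
  p <- c(0.01, 0.02, 0.03)
  expect_equal(adjust_p(p, "BH"), c(0.03, 0.03, 0.03))
  expect_equal(adjust_p(p, "bonferroni"), c(0.03, 0.06, 0.09))
  withr::with_seed(31, {
    for (i in 1:20) {
      pv <- runif(25)
      expect_true(all(adjust_p(pv, "BH") <= adjust_p(pv, "bonferroni") + 1e-12))
      expect_true(all(adjust_p(pv, "BH") >= pv))
    }
  })
})

test_that("over-representation equals the closed-form hypergeometric tail", {
  bg <- sprintf("g%03d", 1:100)
  res <- overrep_test(bg[1:5], gene_sets(list(S = bg[1:5])), bg)
  expect_equal(res$p, 1 / choose(100, 5), tolerance = 1e-12)

  # zero overlap with a tiny set: p ~ 1
  res0 <- overrep_test(bg[1:10], gene_sets(list(S = bg[99:100])), bg)
  expect_gt(res0$p, 0.95)

  # brute-force tail enumeration for backgrounds <= 30
  withr::with_seed(41, {
    for (i in 1:15) {
      N <- sample(10:30, 1)
      bgs <- sprintf("x%02d", seq_len(N))
      q <- sample(bgs, sample(3:min(8, N), 1))
      s <- sample(bgs, sample(2:min(9, N), 1))
      got <- overrep_test(q, gene_sets(list(S = s)), bgs)
      a <- length(intersect(q, s))
      expect_equal(got$p, hyper_tail_p(a, length(s), length(q), N),
                   tolerance = 1e-12)
      expect_equal(got$overlap, a)
    }
  })
  expect_error(overrep_test(c("nope"), gene_sets(list(S = "x01")), "x01"),
               class = "nephromics_stat_error")
})
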