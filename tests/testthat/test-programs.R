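test_that("pathway scores are z-scaled means with degenerate genes dropped", {
  # one gene, clusters [1,2,3]: scaled values are [-1, 0, 1]
  me <- matrix(c(1, 2, 3), 1, 3, dimnames = list("g1", c("c1", "c2", "c3")))
  sm <- pathway_scores(me, gene_sets(list(S = "g1")), degs = "g1")
  expect_equal(unname(sm$scores[, "S"]), c(-1, 0, 1))

  # column scaling invariant: each retained gene has mean 0, sd 1
  withr::with_seed(3, me2 <- matrix(rnorm(40), 8, 5,
                                    dimnames = list(sprintf("g%d", 1:8),
                                                    sprintf("c%d", 1:5))))
  sm2 <- pathway_scores(me2, gene_sets(list(A = rownames(me2)[1:4],
                                            B = rownames(me2)[3:8])),
                        degs = rownames(me2))
  for (nm in c("A", "B")) {
    z <- scale(t(me2[sm2$genes_used[[nm]], ]))
    expect_equal(unname(sm2$scores[, nm]), unname(rowMeans(z)), tolerance = 1e-12)
    expect_lt(abs(mean(sm2$scores[, nm])), 1e-9)
  }

  # identical clusters: sd 0 gene dropped with a warning
  me3 <- rbind(g1 = c(2, 2, 2), g2 = c(1, 2, 3))
  colnames(me3) <- c("c1", "c2", "c3")
  expect_warning(sm3 <- pathway_scores(me3, gene_sets(list(S = c("g1", "g2"))),
                                       degs = c("g1", "g2")),
                 "zero-variance")
  expect_equal(unname(sm3$scores[, "S"]), c(-1, 0, 1))

  # set with no DEGs present scores NA with a message
  expect_message(sm4 <- pathway_scores(me, gene_sets(list(S = "g1", T = "zz")),
                                       degs = "g1"), "no DEGs")
  expect_true(all(is.na(sm4$scores[, "T"])))
})

test_that("subcluster DEGs respect the minimum cluster size and recover programs", {
  sn <- small_cohort()
  norm <- lognormalize(sn$counts)
  degs <- subcluster_degs(norm, min_cells = 50)
  # per-sample clusters of 120 tumor cells split 40/40/40: all skipped at 50
  expect_true(all(lengths(degs) >= 0))
  degs30 <- subcluster_degs(norm, min_cells = 30)
  target <- sprintf("T%02d_c%d", 1:4, sn$truth$programs$target_cluster_index[1])
  hit <- intersect(names(degs30), target)
  expect_gte(length(hit), 3)
  recall <- mean(sn$truth$programs$gene %in% unlist(degs30[hit]))
  expect_gte(recall, 0.8)
  # deterministic ordering
  degs30b <- subcluster_degs(norm, min_cells = 30)
  expect_identical(degs30, degs30b)
})

test_that("module enrichment follows the quantile rules exactly", {
  # 20 clusters with scores equal to ranks: upper 25% = top 5 for a 1-set module
  sc <- matrix(1:20, 20, 1, dimnames = list(sprintf("c%02d", 1:20), "S"))
  sm <- structure(list(scores = sc, cluster_meta = NULL,
                       genes_used = list(S = "g")), class = "score_matrix")
  expect_setequal(module_enrichment(sm, "S", upper_q = 0.75),
                  sprintf("c%02d", 16:20))

  # EMT rule: high pathway score but median epithelial score is excluded
  epi <- setNames(c(1:19, 10), sprintf("c%02d", 1:20))  # c20 epi at median
  emt <- module_enrichment(sm, "S", upper_q = 0.90, epithelial_scores = epi,
                           epi_lower_q = 0.2)
  expect_false("c20" %in% emt)
  epi2 <- setNames(c(1:19, -5), sprintf("c%02d", 1:20)) # c20 epi very low
  expect_true("c20" %in% module_enrichment(sm, "S", upper_q = 0.90,
                                           epithelial_scores = epi2,
                                           epi_lower_q = 0.2))

  # multi-set intersection equals a sort-based oracle on random matrices
  withr::with_seed(9, {
    for (i in 1:10) {
      n <- 24
      sc2 <- matrix(rnorm(n * 3), n, 3,
                    dimnames = list(sprintf("k%02d", 1:n), c("A", "B", "C")))
      smr <- structure(list(scores = sc2, cluster_meta = NULL, genes_used = NULL),
                       class = "score_matrix")
      got <- module_enrichment(smr, c("A", "B", "C"), upper_q = 0.75)
      oracle <- rownames(sc2)[apply(sc2 > rep(apply(sc2, 2, quantile, 0.75, type = 7),
                                              each = n), 1, all)]
      expect_setequal(got, oracle)
    }
  })
})

test_that("epithelial bands partition tumor clusters with EMT precedence", {
  me <- matrix(rep(1:10, each = 2), 2, 10, byrow = FALSE,
               dimnames = list(c("m1", "m2"), sprintf("t%02d", 1:10)))
  me <- me + matrix(c(0, 0.5), 2, 10)
  lab <- epithelial_scores_and_groups(me, c("m1", "m2"),
                                      tumor_clusters = colnames(me))
  # 10 distinct scores: q70 = 7.3, Epi-H = top 3; q40 = 4.6
  expect_setequal(lab$cluster_id[lab$group == "Epi-H"], sprintf("t%02d", 8:10))
  expect_setequal(lab$cluster_id[lab$group == "Epi-M"], sprintf("t%02d", 5:7))
  expect_setequal(lab$cluster_id[lab$group == "Epi-L"], sprintf("t%02d", 1:4))

  # EMT label overrides any band, and labels always partition
  lab2 <- epithelial_scores_and_groups(me, c("m1", "m2"),
                                       tumor_clusters = colnames(me),
                                       emt_clusters = c("t10", "t01"))
  expect_equal(lab2$group[lab2$cluster_id %in% c("t10", "t01")], rep("EMT", 2))
  expect_equal(sort(table(lab2$group), decreasing = TRUE) |> sum(), 10)

  # PT clusters are scored but not labeled
  lab3 <- epithelial_scores_and_groups(me, c("m1", "m2"),
                                       tumor_clusters = colnames(me)[1:8])
  expect_true(all(is.na(lab3$group[lab3$cluster_id %in% c("t09", "t10")])))
  expect_equal(sum(!is.na(lab3$group)), 8)
})

test_that("stage association detects planted shifts and rejects degenerate designs", {
  withr::with_seed(61, {
    clusters <- sprintf("k%02d", 1:24)
    meta <- tibble::tibble(cluster_id = clusters,
                           sample_id = rep(sprintf("P%02d", 1:12), each = 2),
                           n_cells = 100)
    clin <- tibble::tibble(sample_id = sprintf("P%02d", 1:12),
                           stage = rep(c("I", "II", "III", "IV"), 3))
    high <- clin$stage %in% c("III", "IV")
    shift <- rep(ifelse(high, 2, 0), each = 2)
    sc <- cbind(LINKED = rnorm(24, shift, 0.5), FLAT = rnorm(24))
    rownames(sc) <- clusters
    sm <- structure(list(scores = sc, cluster_meta = meta, genes_used = NULL),
                    class = "score_matrix")
    res <- stage_association(sm, clin)
  })
  expect_lt(res$p_adj[res$set == "LINKED"], 0.1)
  expect_equal(res$direction[res$set == "LINKED"], 1)
  expect_gt(res$p[res$set == "FLAT"], 0.05)

  # identical groups: p = 1
  sc1 <- cbind(S = rep(1:2, 12))
  rownames(sc1) <- sprintf("k%02d", 1:24)
  smi <- structure(list(scores = sc1,
                        cluster_meta = tibble::tibble(
                          cluster_id = rownames(sc1),
                          sample_id = rep(sprintf("P%02d", 1:12), each = 2)),
                        genes_used = NULL), class = "score_matrix")
  clin <- tibble::tibble(sample_id = sprintf("P%02d", 1:12),
                         stage = rep(c("I", "III"), 6))
  resi <- stage_association(smi, clin)
  expect_equal(resi$p, 1)

  # single-patient group errors
  clin_bad <- tibble::tibble(sample_id = sprintf("P%02d", 1:12),
                             stage = c("III", rep("I", 11)))
  expect_error(stage_association(smi, clin_bad), class = "nephromics_stat_error")
})
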