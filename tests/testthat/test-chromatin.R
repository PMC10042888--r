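test_that("peak resize and greedy dedup match the brute-force oracle", {
  # two overlapping peaks: keep the stronger
  p2 <- peak_table(tibble::tibble(chrom = "chr1", start = c(100, 300),
                                  end = c(601, 801), summit = c(350, 550),
                                  score = c(5, 3)))
  expect_equal(dedup_peaks(p2)$score, 5)
  # chain A > B > C with A~B and B~C but not A~C: keep A and C
  p3 <- peak_table(tibble::tibble(chrom = "chr1",
                                  start = c(100, 400, 700),
                                  end = c(601, 901, 1201),
                                  summit = c(350, 650, 950),
                                  score = c(9, 5, 3)))
  expect_setequal(dedup_peaks(p3)$score, c(9, 3))
  # disjoint input unchanged
  pd <- peak_table(tibble::tibble(chrom = "chr1", start = c(0, 1000),
                                  end = c(501, 1501), summit = c(250, 1250),
                                  score = c(1, 2)))
  expect_equal(nrow(dedup_peaks(pd)), 2)

  # resize: 501 bp centered at summit
  rs <- resize_peaks(p2)
  expect_true(all(rs$end - rs$start == 501))
  expect_equal(rs$start, rs$summit - 250)

  # random instances (<= 100 peaks) equal the O(n^2) greedy oracle,
  # and the output is non-overlapping by interval sweep
  for (seed in 1:8) {
    pk <- resize_peaks(random_peaks(sample(20:100, 1), seed = seed))
    got <- dedup_peaks(pk) |> dplyr::arrange(.data$chrom, .data$start)
    oracle <- brute_dedup(pk)
    expect_equal(as.data.frame(got), as.data.frame(oracle))
    by_chr <- split(got, got$chrom)
    for (g in by_chr) expect_true(all(diff(g$start) >= 501))
  }
})

test_that("gene activity equals brute-force interval overlap", {
  genes <- gene_model(tibble::tibble(
    gene_id = c("gA", "gB"), chrom = "chr1", strand = c("+", "-"),
    start = c(5000, 12000), end = c(6000, 13000)
  ))
  # + strand window [3000, 6000]: read/peak at 3100 counted
  pk <- peak_table(tibble::tibble(chrom = "chr1",
                                  start = c(3050, 2500, 12950, 14500),
                                  end = c(3151, 2901, 13051, 15001)))
  cnt <- matrix(c(2, 1, 3, 4, 5, 1, 7, 2), 4, 2)
  pm <- peak_matrix(cnt, pk, c("c1", "c2"),
                    tibble::tibble(sample_id = c("S", "S"), frip = c(0.5, 0.5)))
  act <- gene_activity(pm, genes)
  # gA window [3000,6000]: overlaps peak1 (3051-3151) only (peak2 ends at 2901)
  expect_equal(as.numeric(act$counts["gA", ]), as.numeric(cnt[1, ]))
  # gB is - strand: window [12000, 15000]: peaks 3 and 4
  expect_equal(as.numeric(act$counts["gB", ]), as.numeric(cnt[3, ] + cnt[4, ]))

  withr::with_seed(15, {
    rg <- gene_model(tibble::tibble(
      gene_id = sprintf("g%02d", 1:12), chrom = sample(c("chr1", "chr2"), 12, TRUE),
      strand = sample(c("+", "-"), 12, TRUE),
      start = st <- sample.int(4e4, 12), end = st + sample.int(8000, 12)
    ))
    rpk <- random_peaks(40, seed = 16)
    rcnt <- matrix(rpois(40 * 6, 2), 40, 6)
    rpm <- peak_matrix(rcnt, rpk, sprintf("c%d", 1:6),
                       tibble::tibble(sample_id = rep("S", 6), frip = 0.5))
  })
  got <- as.matrix(gene_activity(rpm, rg)$counts)
  expect_equal(unname(got), unname(brute_gene_activity(rpm, rg)))
})

test_that("promoter windows follow the (-1000, +100) strand-aware rule", {
  gm <- gene_model(tibble::tibble(gene_id = c("gp", "gm"), chrom = "chr1",
                                  strand = c("+", "-"), start = c(5000, 3000),
                                  end = c(9000, 5000)))
  pr <- annotate_promoters(gm)
  expect_equal(pr$prom_start[pr$gene_id == "gp"], 4000)   # tss 5000, + strand
  expect_equal(pr$prom_end[pr$gene_id == "gp"], 5100)
  expect_equal(pr$prom_start[pr$gene_id == "gm"], 4900)   # tss 5000, - strand
  expect_equal(pr$prom_end[pr$gene_id == "gm"], 6000)

  # classification: promoter overlap + nearest-gene tiebreak by distance then id
  pk <- peak_table(tibble::tibble(chrom = "chr1", start = c(4450, 20000),
                                  end = c(4951, 20501)))
  cls <- classify_peaks(pk, gm)
  expect_equal(cls$class, c("promoter", "distal"))
  # both genes have tss 5000: equidistant, tie broken by gene id
  expect_equal(cls$nearest_gene[1], "gm")
  # distal peak starts at 1-based 20001; tss at 5000
  expect_equal(cls$tss_distance[2], 15001)
})

test_that("motif scanning matches exhaustive enumeration, thresholds and strand symmetry", {
  # non-palindromic consensus ACGG (probability-1 columns)
  acgg <- pwm(matrix(c(1, 0, 0, 0,  0, 1, 0, 0,  0, 0, 1, 0,  0, 0, 1, 0), 4, 4),
              "ACGG")
  # perfect match scores 4 * log2(4) = 8 bits; one hit at offset 2 on +
  hits <- scan_motifs(acgg, c(s1 = "TTACGGTT"), p_threshold = 5e-3)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$offset, 2L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$score, 8)
  # reverse-complement sequence gives the same hit on the - strand
  hits_rc <- scan_motifs(acgg, c(s1 = "AACCGTAA"), p_threshold = 5e-3)
  expect_equal(hits_rc$strand, "-")
  expect_equal(hits_rc$score, 8)
  # windows containing N are skipped
  hits_n <- scan_motifs(acgg, c(s1 = "TTACGNTT"), p_threshold = 5e-3)
  expect_equal(nrow(hits_n), 0)

  # DP threshold equals full score-distribution enumeration for L <= 8
  withr::with_seed(25, {
    for (L in c(4, 6, 8)) {
      m <- matrix(runif(4 * L, 0.05, 1), 4, L)
      p <- pwm(m, sprintf("R%d", L))
      expect_equal(pwm_score_threshold(p, 5e-4), enum_score_threshold(p, 5e-4),
                   tolerance = 5e-3)
    }
  })

  # hits and scores identical to brute-force all-window enumeration
  withr::with_seed(26, {
    seqs <- setNames(vapply(1:20, function(i) {
      paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
    }, character(1)), sprintf("s%02d", 1:20))
    m <- matrix(runif(4 * 7, 0.05, 1), 4, 7)
    p <- pwm(m, "R7")
  })
  thr <- pwm_score_threshold(p, 1e-3)
  got <- scan_motifs(p, seqs, p_threshold = 1e-3)
  for (nm in names(seqs)) {
    oracle <- brute_scan(p, seqs[[nm]], thr)
    sub <- got[got$seq_id == nm, c("offset", "strand", "score")] |>
      dplyr::arrange(.data$offset, .data$strand)
    if (nrow(oracle)) {
      oracle <- dplyr::arrange(oracle, .data$offset, .data$strand)
      expect_equal(as.data.frame(sub), as.data.frame(oracle), tolerance = 1e-10)
    } else {
      expect_equal(nrow(sub), 0)
    }
  }
})

test_that("DACR consensus applies the 50% significance and direction rules", {
  # constructed result check via a small planted layer
  cfg <- cohort_config(seed = 33, n_tumor_samples = 6, n_mutant_samples = 2,
                       n_peaks = 120, n_planted_dacrs = 15, dacr_log2fc = -1.2,
                       atac_cells_per_sample = c(Tumor = 120, PT = 20),
                       n_genes = 300, n_planted_markers = 5,
                       n_program_genes = 0, n_type_markers = 20,
                       n_motif_peaks = 10)
  atac <- gen_atac_layer(cfg)
  res <- dacr_consensus(atac$peaks, atac$truth$mutant_samples,
                        atac$truth$control_samples)
  # invariant: final pass implies >= 50% significant and consistent direction
  expect_true(all(res$n_significant[res$final_pass] /
                    res$n_compared[res$final_pass] >= 0.5))
  expect_true(all(res$consistent_direction[res$final_pass]))
  truth <- atac$truth$dacrs$peak_id
  expect_gte(mean(truth %in% res$peak_id[res$final_pass]), 0.8)
  expect_equal(unique(res$direction[res$peak_id %in% truth & res$final_pass]), -1)

  # direction-flipped plants are always rejected
  cfg_flip <- cohort_config(seed = 34, n_tumor_samples = 6, n_mutant_samples = 4,
                            n_peaks = 120, n_planted_dacrs = 15,
                            dacr_direction = "flip", dacr_log2fc = -1.2,
                            atac_cells_per_sample = c(Tumor = 120, PT = 20),
                            n_genes = 300, n_planted_markers = 5,
                            n_program_genes = 0, n_type_markers = 20,
                            n_motif_peaks = 10)
  atf <- gen_atac_layer(cfg_flip)
  rf <- dacr_consensus(atf$peaks, atf$truth$mutant_samples,
                       atf$truth$control_samples)
  expect_equal(sum(rf$final_pass[rf$peak_id %in% atf$truth$dacrs$peak_id]), 0)

  expect_error(dacr_consensus(atac$peaks, atac$truth$mutant_samples[1],
                              atac$truth$control_samples),
               class = "nephromics_stat_error")
})

test_that("CNV correction removes copy-number-driven peaks", {
  cfg <- cohort_config(seed = 35, n_tumor_samples = 6, n_mutant_samples = 3,
                       n_peaks = 150, n_planted_dacrs = 12, dacr_log2fc = -1.2,
                       n_cnv_peaks = 12, cnv_peak_log2cr = 1.2,
                       atac_cells_per_sample = c(Tumor = 120, PT = 20),
                       n_genes = 300, n_planted_markers = 5,
                       n_program_genes = 0, n_type_markers = 20,
                       n_motif_peaks = 10)
  atac <- gen_atac_layer(cfg)
  res <- dacr_consensus(atac$peaks, atac$truth$mutant_samples,
                        atac$truth$control_samples,
                        cnv_values = atac$cnv_values)
  cnv_peaks <- atac$truth$cnv_peaks$peak_id
  true_peaks <- atac$truth$dacrs$peak_id
  # copy-driven peaks are dropped by the corrected test ...
  expect_lte(sum(res$final_pass[res$peak_id %in% cnv_peaks]), 2)
  # ... while genuinely regulated peaks survive it
  expect_gte(mean(true_peaks %in% res$peak_id[res$final_pass]), 0.75)
})

test_that("motif-to-gene mapping categorizes promoter vs distant with enhancers", {
  genes <- gene_model(tibble::tibble(gene_id = "gX", chrom = "chr1",
                                     strand = "+", start = 10000, end = 15000))
  # promoter window [9000, 10100]
  dacrs <- peak_table(tibble::tibble(
    chrom = "chr1", start = c(9800, 4800, 3000),
    end = c(10301, 5301, 3501)
  ))
  hits <- tibble::tibble(
    motif_id = "M1", seq_id = dacrs$peak_id[c(1, 2, 3)],
    offset = c(249L, 100L, 50L), strand = "+", score = 10
  )
  class(hits) <- c("motif_hits", class(hits))
  co <- tibble::tibble(peak1 = dacrs$peak_id[1],
                       peak2 = dacrs$peak_id[2:3],
                       coaccess = c(0.3, 0.2))
  edges <- map_motifs_to_genes(dacrs, genes, hits,
                               motif_lengths = c(M1 = 8L), coaccess = co)
  # hit at 9800+249+1 = 10050 inside the promoter -> promoter motif
  e1 <- edges[edges$peak_id == dacrs$peak_id[1], ]
  expect_equal(e1$category, "promoter")
  expect_false(e1$enhancer)
  # co-accessibility 0.3 links the 5 kb-upstream DACR: distant + enhancer
  e2 <- edges[edges$peak_id == dacrs$peak_id[2], ]
  expect_equal(e2$category, "distant")
  expect_true(e2$enhancer)
  # co-accessibility 0.2 stays below the cutoff: no edge
  expect_false(dacrs$peak_id[3] %in% edges$peak_id)
  # genes without promoter DACRs yield no edges
  genes_far <- gene_model(tibble::tibble(gene_id = "gY", chrom = "chr2",
                                         strand = "+", start = 1e6, end = 1.1e6))
  expect_equal(nrow(map_motifs_to_genes(dacrs, genes_far, hits)), 0)
})

test_that("motif deviations are conserved and detect planted group shifts", {
  cfg <- cohort_config(seed = 36, n_tumor_samples = 4, n_mutant_samples = 2,
                       n_peaks = 100, n_planted_dacrs = 20, dacr_log2fc = -1.5,
                       atac_cells_per_sample = c(Tumor = 80, PT = 40),
                       n_genes = 300, n_planted_markers = 5,
                       n_program_genes = 0, n_type_markers = 20,
                       n_motif_peaks = 10)
  atac <- gen_atac_layer(cfg)
  pm <- atac$peaks
  # motif covering all peaks: raw deviation identically zero
  raw <- motif_deviation_scores(pm, list(ALL = pm$gene_ids), standardize = FALSE)
  expect_equal(max(abs(raw)), 0)
  # motif on the down-planted peaks: mutant tumor cells score lower
  dev <- motif_deviation_scores(pm, list(D = atac$truth$dacrs$peak_id),
                                n_background = 25)
  meta <- pm$cell_meta
  mut <- meta$group_label == "mutant" & meta$cell_type == "Tumor"
  ctl <- meta$group_label == "nonmutant" & meta$cell_type == "Tumor"
  expect_lt(mean(dev["D", mut]), mean(dev["D", ctl]))

  # per-sample differential tiers: identical groups flag nothing
  devnull <- matrix(rnorm(2 * sum(mut | ctl)), 2,
                    dimnames = list(c("a", "b"), NULL))
  dm0 <- differential_motifs(devnull, meta[mut | ctl, ],
                             tumor_type = "Tumor", ref_type = "Tumor")
  expect_equal(sum(dm0$pass_half), 0)

  dm <- differential_motifs(dev, meta, tumor_type = "Tumor", ref_type = "PT")
  expect_true(is.data.frame(dm))
  expect_true(all(dm$n_significant <= dm$n_compared))
  expect_true(all(!dm$pass_all | dm$pass_half))  # strict tier implies half tier
})
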