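# Hand-built DE tables for rule-instantiation checks.
fake_de <- function(genes, lfc, p_adj) {
  out <- tibble::tibble(gene = genes, lfc = lfc, pct1 = 0.5, pct2 = 0.1,
                        p = p_adj, p_adj = p_adj, direction = sign(lfc),
                        filtered_reason = NA_character_)
  class(out) <- c("de_result", class(out))
  out
}

test_that("stage-1 criteria follow the stated sample-fraction rules", {
  genes <- c("gA", "gB")
  samples <- sprintf("S%02d", 1:10)
  # gA: up+significant vs all types in sample 1; up in 9/10 vs combined,
  # significant in 8/10; up in NAT -> pass
  # gB: up in 9/10 but significant in only 7/10 (70% < 75%) -> fail c2
  vs_type <- setNames(lapply(samples, function(s) {
    if (s == "S01") {
      list(PT = fake_de(genes, c(1, 1), c(0.01, 0.01)),
           Immune = fake_de(genes, c(1, 1), c(0.01, 0.01)))
    } else {
      list(PT = fake_de(genes, c(1, 1), c(0.5, 0.5)))
    }
  }), samples)
  vs_nontumor <- setNames(lapply(seq_along(samples), function(i) {
    lfc_a <- if (i <= 9) 1 else -1
    p_a <- if (i <= 8) 0.01 else 0.5
    lfc_b <- if (i <= 9) 1 else -1
    p_b <- if (i <= 7) 0.01 else 0.5
    fake_de(genes, c(lfc_a, lfc_b), c(p_a, p_b))
  }), samples)
  tabs <- list(vs_type = vs_type, vs_nontumor = vs_nontumor,
               vs_nat = fake_de(genes, c(1, 1), c(0.2, 0.2)),
               samples_used = samples)
  s1 <- stage1_tumor_specific(tabs)
  expect_true(s1$stage1_pass[s1$gene == "gA"])
  expect_false(s1$stage1_pass[s1$gene == "gB"])
  expect_false(s1$c2[s1$gene == "gB"])
  expect_true(s1$c1[s1$gene == "gB"])  # fails only the c2 fraction rule
})

test_that("marker consensus recovers planted markers on a small cohort", {
  sn <- small_cohort()
  norm <- lognormalize(sn$counts)
  s1 <- stage1_tumor_specific(tumor_marker_de_tables(norm))
  called <- s1$gene[s1$stage1_pass]
  truth <- sn$truth$markers$gene
  expect_gte(mean(truth %in% called), 0.8)
  expect_gte(mean(called %in% truth), 0.8)

  # stage 2 keeps tumor-exclusive genes; empty input gives empty output
  s2 <- stage2_epithelial_exclusion(called, norm)
  expect_gte(mean(s2 %in% truth), 0.8)
  expect_identical(stage2_epithelial_exclusion(character(), norm), character())

  # a PT identity gene forced through stage 1 is excluded by stage 2
  pt_gene <- sn$truth$type_markers$gene[sn$truth$type_markers$cell_type == "PT"][1]
  expect_false(pt_gene %in% stage2_epithelial_exclusion(c(called, pt_gene), norm))
})

test_that("stage 3 applies a strict activity-fold threshold", {
  withr::with_seed(44, cnt <- matrix(rpois(40 * 60, 2) + 1, 40, 60))
  act <- tiny_norm(cnt, cell_types = rep(c("Tumor", "PT"), each = 30))
  # force gene 1 to identical tumor/non-tumor activity: fold exactly 1
  act$values[1, ] <- rep(1, 60)
  s3 <- stage3_atac_support(c(act$gene_ids[1], "absent_gene"), act)
  expect_false(s3$pass[1])                     # fold 1.0 excluded (strict >)
  expect_true(is.na(s3$activity_fc[2]))        # missing gene flagged
  expect_false(s3$pass[2])
})

test_that("stage 4 validates planted bulk shifts and calibrates on nulls", {
  cfg <- cohort_config(seed = 51, n_genes = 400, n_planted_markers = 25,
                       n_program_genes = 0, n_type_markers = 20,
                       n_bulk_tumor = 60, n_bulk_nat = 20, bulk_shift_log2 = 1)
  bs <- gen_bulk_survival(cfg)
  truth <- gen_sn_cohort(cfg)$truth$markers$gene
  nulls <- setdiff(rownames(bs$cohort$expr), truth)[1:100]
  s4 <- stage4_bulk_validation(c(truth, nulls), bs$cohort)
  expect_gte(mean(s4$bulk_rna_pass[s4$gene %in% truth]), 0.95)
  expect_lte(mean(s4$bulk_rna_pass[s4$gene %in% nulls]), 0.07)
  # protein layer passes for planted genes that have protein rows
  prot <- s4$protein_pass[s4$gene %in% truth]
  expect_gte(mean(prot, na.rm = TRUE), 0.75)
  # genes without protein rows get NA protein flags
  missing_prot <- setdiff(rownames(bs$cohort$expr), rownames(bs$cohort$protein))
  if (length(missing_prot)) {
    s4m <- stage4_bulk_validation(missing_prot[1], bs$cohort)
    expect_true(is.na(s4m$protein_pass[1]))
  }
})

test_that("tier structure is monotone in the evidence layers", {
  sn <- small_cohort()
  norm <- lognormalize(sn$counts)
  cfg <- cohort_config(seed = 7, n_genes = 600, n_planted_markers = 20,
                       n_program_genes = 15, n_type_markers = 30,
                       n_bulk_tumor = 40, n_bulk_nat = 15)
  bulk <- gen_bulk_survival(cfg)$cohort
  atac <- gen_atac_layer(cohort_config(
    seed = 7, n_genes = 600, n_planted_markers = 20, n_program_genes = 15,
    n_type_markers = 30, n_peaks = 80, n_planted_dacrs = 0, n_motif_peaks = 5,
    atac_cells_per_sample = c(Tumor = 60, PT = 30)
  ))
  act <- lognormalize(atac$activity)
  rep_full <- discover_tumor_markers(norm, act, bulk)
  expect_true(all(rep_full$final_tier %in% 0:4))
  # tier k implies all lower stages passed
  expect_true(all(rep_full$stage1_pass[rep_full$final_tier >= 1]))
  expect_true(all(rep_full$stage2_pass[rep_full$final_tier >= 2]))
  expect_true(all(rep_full$stage3_pass[rep_full$final_tier >= 3]))
  # removing an evidence layer never raises the tier
  rep_noatac <- discover_tumor_markers(norm, NULL, bulk)
  common <- intersect(rep_full$gene, rep_noatac$gene)
  expect_true(all(rep_noatac$final_tier[match(common, rep_noatac$gene)] <=
                    pmax(rep_full$final_tier[match(common, rep_full$gene)], 2)))
  # planted markers reach the top tier in numbers
  expect_gte(sum(rep_full$final_tier == 4 &
                   rep_full$gene %in% sn$truth$markers$gene), 10)
})

test_that("raising a planted marker's effect never removes it from stage 1", {
  base <- list(seed = 77, n_tumor_samples = 4, n_nat_samples = 1,
               cells_per_sample_by_type = c(Tumor = 100, PT = 50, Immune = 30,
                                            Endothelial = 30),
               nat_cells_by_type = c(PT = 50, Immune = 20, Endothelial = 20),
               n_genes = 400, n_planted_markers = 10, n_program_genes = 0,
               n_type_markers = 20)
  called <- lapply(c(1, 1.5, 2.5), function(fc) {
    sn <- gen_sn_cohort(do.call(cohort_config, c(base, marker_log2fc = fc)))
    s1 <- stage1_tumor_specific(tumor_marker_de_tables(lognormalize(sn$counts)))
    intersect(s1$gene[s1$stage1_pass], sn$truth$markers$gene)
  })
  expect_true(all(called[[1]] %in% called[[2]]))
  expect_true(all(called[[2]] %in% called[[3]]))
})

test_that("cell-type markers and group correlations behave", {
  sn <- small_cohort()
  norm <- lognormalize(sn$counts)
  tops <- celltype_top_markers(norm, k = 30,
                               types = c("PT", "Immune", "Endothelial"))
  tm <- sn$truth$type_markers
  for (ty in names(tops)) {
    expect_gte(mean(tops[[ty]] %in% tm$gene[tm$cell_type == ty]), 0.8)
  }
  # k larger than passing genes yields a shorter list with a message
  expect_message(short <- celltype_top_markers(norm, k = 5000, types = "PT"),
                 "positive markers")
  expect_lt(length(short$PT), 5000)

  gm <- group_mean_expression(norm, "cell_type")
  cc <- celltype_correlation(gm, tops)
  expect_equal(diag(cc), setNames(rep(1, ncol(gm)), colnames(gm)))
  expect_equal(cc, t(cc))
  # duplicated group correlates at 1
  gm2 <- cbind(gm, DUP = gm[, "PT"])
  cc2 <- celltype_correlation(gm2, tops)
  expect_equal(cc2["PT", "DUP"], 1)

  # closed-form 3-gene check against cor()
  m <- matrix(c(1, 2, 3, 6, 5, 4, 2, 2, 8), nrow = 3,
              dimnames = list(c("x1", "x2", "x3"), c("G1", "G2", "G3")))
  got <- celltype_correlation(m, list(all = rownames(m)))
  expect_equal(got, cor(m))
})
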