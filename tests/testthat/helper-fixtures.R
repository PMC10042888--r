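# Shared small fixtures, built in code. Larger cohorts are generated inside
# the tests that need them.

# A tiny norm_matrix from an explicit dense count matrix (one sample unless
# meta is given).
tiny_norm <- function(counts, cell_types = NULL, sample_id = "S1",
                      cluster_id = NULL, group_label = "tumor",
                      scale_factor = 1e4) {
  n_c <- ncol(counts)
  rownames(counts) <- rownames(counts) %||% sprintf("g%02d", seq_len(nrow(counts)))
  colnames(counts) <- colnames(counts) %||% sprintf("c%02d", seq_len(n_c))
  meta <- tibble::tibble(
    sample_id = rep_len(sample_id, n_c),
    cell_type = if (is.null(cell_types)) rep("Tumor", n_c) else cell_types,
    cluster_id = if (is.null(cluster_id)) rep(NA_character_, n_c) else cluster_id,
    group_label = rep_len(group_label, n_c)
  )
  lognormalize(sn_counts(counts, rownames(counts), colnames(counts), meta),
               scale_factor = scale_factor)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small cohort shared by several unit tests (cached across test files).
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- gen_sn_cohort(cohort_config(
        seed = 7, n_tumor_samples = 4, n_nat_samples = 1,
        cells_per_sample_by_type = c(Tumor = 120, PT = 60, Immune = 40, Endothelial = 40),
        nat_cells_by_type = c(PT = 80, Immune = 30, Endothelial = 30),
        n_genes = 600, n_planted_markers = 20, n_program_genes = 15,
        n_type_markers = 30, program_log2fc = 1.5
      ))
    }
    cache
  }
})

random_peaks <- function(n, seed = 1, chroms = c("chr1", "chr2")) {
  withr::with_seed(seed, {
    summit <- round(runif(n, 500, 5e4))
    peak_table(tibble::tibble(
      chrom = sample(chroms, n, replace = TRUE),
      start = summit - 250, end = summit + 251, summit = summit,
      score = round(runif(n, 1, 10), 3)
    ))
  })
}
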