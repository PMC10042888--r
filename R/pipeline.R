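#' @importFrom jsonlite write_json read_json
NULL

pipeline_subcommands <- c("simulate", "markers", "programs", "signature",
                          "chromatin", "cnv", "report")

# Allowed config keys per subcommand; unknown keys are rejected.
pipeline_keys <- function() list(
  simulate = names(formals(cohort_config)),
  markers = c("mtx", "genes", "cells", "meta", "activity_mtx", "activity_cells",
              "activity_meta", "bulk_expr", "bulk_clinical", "bulk_protein",
              "p_cut", "frac_up", "frac_sig", "min_pct", "min_diff_pct"),
  programs = c("mtx", "genes", "cells", "meta", "gmt", "min_cells", "p_cut",
               "upper_q"),
  signature = c("mtx", "genes", "cells", "meta", "gmt", "set", "markers_file",
                "bulk_expr", "bulk_clinical", "lo_q", "hi_q", "top_q", "bottom_q",
                "min_cells"),
  chromatin = c("peak_mtx", "peaks_bed", "peak_ids", "peak_cells", "peak_meta", "genes_tsv",
                "fasta", "pfm", "coaccess", "cnv_tsv", "mutant_samples",
                "control_samples", "p_threshold", "p_cut", "min_frac"),
  cnv = c("segments", "arm_map", "gain", "loss"),
  report = c("manifests")
)

check_keys <- function(subcommand, config) {
  extra <- setdiff(names(config), pipeline_keys()[[subcommand]])
  if (length(extra)) {
    abort(sprintf("unknown config key(s) for '%s': %s", subcommand,
                  paste(extra, collapse = ", ")),
          class = "nephromics_config_error")
  }
}

need_file <- function(config, key, outdir = NULL, default = NULL) {
  path <- config[[key]] %||% (if (!is.null(default) && !is.null(outdir))
    file.path(outdir, default) else NULL)
  if (is.null(path)) {
    abort(sprintf("missing required config key '%s'", key),
          class = "nephromics_config_error")
  }
  if (!file.exists(path)) {
    abort(sprintf("config key '%s': file not found: %s", key, path),
          class = "nephromics_config_error")
  }
  path
}

#' Run a pipeline stage
#'
#' Orchestrates the package's stages behind named subcommands with a single
#' structured config (a named list or the path of a YAML file), deterministic
#' seeding, and a machine-readable run manifest. Identical config and seed
#' produce byte-identical TSV outputs. Unknown config keys are rejected.
#'
#' Subcommands: `simulate` (write a full synthetic cohort), `markers`
#' (tiered marker consensus), `programs` (subcluster DEGs and pathway
#' scores), `signature` (intrinsic signature, bulk scoring, survival
#' stratification), `chromatin` (DACR consensus, motif scan and mapping),
#' `cnv` (segment and arm-level calls), `report` (summarize manifests).
#'
#' @param subcommand one of the subcommands above.
#' @param config named list or YAML file path; file inputs default to the
#'   `simulate` output names inside `outdir` where sensible.
#' @param seed integer master seed.
#' @param outdir output directory (created if absent).
#' @return invisibly, a list of the stage's main results; artifacts and a
#'   `manifest_<subcommand>.json` are written under `outdir`.
#' @export
run_pipeline <- function(subcommand, config = list(), seed = 1L, outdir = ".") {
  subcommand <- match.arg(subcommand, pipeline_subcommands)
  if (is.character(config) && length(config) == 1) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  check_keys(subcommand, config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  res <- switch(subcommand,
    simulate = pipe_simulate(config, seed, outdir),
    markers = pipe_markers(config, seed, outdir),
    programs = pipe_programs(config, seed, outdir),
    signature = pipe_signature(config, seed, outdir),
    chromatin = pipe_chromatin(config, seed, outdir),
    cnv = pipe_cnv(config, seed, outdir),
    report = pipe_report(config, seed, outdir)
  )
  manifest <- list(
    subcommand = subcommand, seed = seed,
    package_version = as.character(utils::packageVersion("nephromics")),
    config = config, outputs = res$outputs
  )
  write_json(manifest, file.path(outdir, sprintf("manifest_%s.json", subcommand)),
             auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}

pipe_simulate <- function(config, seed, outdir) {
  # YAML represents named numeric vectors as maps; flatten scalar lists back
  config <- lapply(config, function(x) {
    if (is.list(x) && length(x) && all(lengths(x) == 1) &&
        all(vapply(x, is.numeric, logical(1)))) unlist(x) else x
  })
  cfg <- do.call(cohort_config, c(list(seed = seed), config))
  sn <- gen_sn_cohort(cfg)
  atac <- gen_atac_layer(cfg)
  bulk <- gen_bulk_survival(cfg)
  segs <- gen_segments(cfg)
  genes <- gen_gene_models(cfg)
  p <- function(f) file.path(outdir, f)
  write_count_matrix(sn$counts, p("sn.mtx"), p("sn_genes.tsv"), p("sn_cells.tsv"),
                     p("sn_meta.tsv"))
  write_count_matrix(atac$activity, p("activity.mtx"), p("sn_genes.tsv"),
                     p("activity_cells.tsv"), p("activity_meta.tsv"))
  write_count_matrix(atac$peaks, p("peaks.mtx"), p("peak_ids.tsv"),
                     p("peak_cells.tsv"), p("peak_meta.tsv"))
  write_peaks_bed(atac$peaks$peaks, p("peaks.bed"))
  write_fasta(atac$sequences, p("peaks.fasta"))
  write_jaspar_pfm(atac$pwms, p("motifs.pfm"))
  write_bulk(bulk$cohort, p("bulk_expr.tsv"), p("bulk_clinical.tsv"),
             p("bulk_protein.tsv"))
  write_segments(segs$segments, p("segments.tsv"))
  readr::write_tsv(genes, p("gene_models.tsv"))
  readr::write_tsv(toy_arm_map(), p("arm_map.tsv"))
  readr::write_tsv(as_tibble(atac$cnv_values, rownames = "peak_id"),
                   p("cnv_values.tsv"))
  sets <- gene_sets(list(
    PLANTED_PROGRAM = sn$truth$programs$gene %||% sn$truth$markers$gene,
    EPITHELIAL_PT = sn$truth$type_markers$gene[sn$truth$type_markers$cell_type == "PT"],
    RANDOM_A = sprintf("g%04d", seq(401, 430)),
    RANDOM_B = sprintf("g%04d", seq(431, 460))
  ))
  write_gmt(sets, p("gene_sets.gmt"))
  readr::write_tsv(sn$truth$markers, p("truth_markers.tsv"))
  readr::write_tsv(atac$truth$dacrs, p("truth_dacrs.tsv"))
  readr::write_tsv(atac$truth$motifs, p("truth_motifs.tsv"))
  list(outputs = c("sn.mtx", "activity.mtx", "peaks.mtx", "peaks.bed",
                   "peaks.fasta", "motifs.pfm", "bulk_expr.tsv",
                   "bulk_clinical.tsv", "bulk_protein.tsv", "segments.tsv",
                   "gene_models.tsv", "arm_map.tsv", "cnv_values.tsv",
                   "gene_sets.gmt", "truth_markers.tsv", "truth_dacrs.tsv",
                   "truth_motifs.tsv"))
}

read_sn_from_config <- function(config, outdir, prefix = "sn") {
  read_count_matrix(
    need_file(config, "mtx", outdir, paste0(prefix, ".mtx")),
    need_file(config, "genes", outdir, paste0(prefix, "_genes.tsv")),
    need_file(config, "cells", outdir, paste0(prefix, "_cells.tsv")),
    need_file(config, "meta", outdir, paste0(prefix, "_meta.tsv"))
  )
}

pipe_markers <- function(config, seed, outdir) {
  sn <- read_sn_from_config(config, outdir)
  norm <- lognormalize(sn)
  activity <- NULL
  if (!is.null(config$activity_mtx) || file.exists(file.path(outdir, "activity.mtx"))) {
    act <- read_count_matrix(
      need_file(config, "activity_mtx", outdir, "activity.mtx"),
      need_file(config, "genes", outdir, "sn_genes.tsv"),
      need_file(config, "activity_cells", outdir, "activity_cells.tsv"),
      need_file(config, "activity_meta", outdir, "activity_meta.tsv")
    )
    activity <- lognormalize(act)
  }
  bulk <- NULL
  if (!is.null(config$bulk_expr) || file.exists(file.path(outdir, "bulk_expr.tsv"))) {
    bulk <- read_bulk(
      need_file(config, "bulk_expr", outdir, "bulk_expr.tsv"),
      need_file(config, "bulk_clinical", outdir, "bulk_clinical.tsv"),
      tryCatch(need_file(config, "bulk_protein", outdir, "bulk_protein.tsv"),
               error = function(e) NULL)
    )
  }
  report <- discover_tumor_markers(norm, activity, bulk)
  readr::write_tsv(report, file.path(outdir, "marker_report.tsv"))
  for (k in 1:4) {
    writeLines(report$gene[report$final_tier >= k],
               file.path(outdir, sprintf("markers_tier%d.txt", k)))
  }
  list(report = report,
       outputs = c("marker_report.tsv", sprintf("markers_tier%d.txt", 1:4)))
}

pipe_programs <- function(config, seed, outdir) {
  sn <- read_sn_from_config(config, outdir)
  norm <- lognormalize(sn)
  sets <- read_gmt(need_file(config, "gmt", outdir, "gene_sets.gmt"))
  degs <- subcluster_degs(norm, min_cells = config$min_cells %||% 50,
                          p_cut = config$p_cut %||% 0.05)
  cm <- cluster_mean_expression(norm, min_cells = config$min_cells %||% 50)
  sm <- suppressWarnings(pathway_scores(cm$mean_expr, sets, degs, cm$cluster_meta))
  deg_tbl <- purrr::map_dfr(names(degs), function(cl) {
    tibble(cluster_id = cl, gene = degs[[cl]])
  })
  readr::write_tsv(deg_tbl, file.path(outdir, "subcluster_degs.tsv"))
  readr::write_tsv(as_tibble(sm$scores, rownames = "cluster_id"),
                   file.path(outdir, "pathway_scores.tsv"))
  enriched <- purrr::map_dfr(colnames(sm$scores), function(nm) {
    cl <- module_enrichment(sm, nm, upper_q = config$upper_q %||% 0.75)
    if (length(cl)) tibble(set = nm, cluster_id = cl) else NULL
  })
  readr::write_tsv(enriched, file.path(outdir, "module_enrichment.tsv"))
  list(scores = sm, degs = degs,
       outputs = c("subcluster_degs.tsv", "pathway_scores.tsv",
                   "module_enrichment.tsv"))
}

pipe_signature <- function(config, seed, outdir) {
  sn <- read_sn_from_config(config, outdir)
  norm <- lognormalize(sn)
  sets <- read_gmt(need_file(config, "gmt", outdir, "gene_sets.gmt"))
  set_name <- config$set %||% names(sets)[1]
  if (!set_name %in% names(sets)) {
    abort(sprintf("set '%s' not in GMT", set_name), class = "nephromics_config_error")
  }
  markers <- readLines(need_file(config, "markers_file", outdir, "markers_tier1.txt"))
  min_cells <- config$min_cells %||% 50
  degs <- subcluster_degs(norm, min_cells = min_cells)
  cm <- cluster_mean_expression(norm, min_cells = min_cells)
  sm <- suppressWarnings(pathway_scores(cm$mean_expr, sets[set_name], degs,
                                        cm$cluster_meta))
  scores <- setNames(sm$scores[, set_name], rownames(sm$scores))
  sig <- build_intrinsic_signature(norm, scores, markers,
                                   top_q = config$top_q %||% 0.9,
                                   bottom_q = config$bottom_q %||% 0.1)
  bulk <- read_bulk(need_file(config, "bulk_expr", outdir, "bulk_expr.tsv"),
                    need_file(config, "bulk_clinical", outdir, "bulk_clinical.tsv"))
  outputs <- c("signature_genes.txt")
  writeLines(sig, file.path(outdir, "signature_genes.txt"))
  fit <- NULL
  if (length(sig)) {
    ss <- bulk_signature_score(bulk, sig)
    fit <- quantile_stratified_survival(ss, bulk$clinical,
                                        lo_q = config$lo_q %||% 0.25,
                                        hi_q = config$hi_q %||% 0.75)
    readr::write_tsv(ss, file.path(outdir, "signature_scores.tsv"))
    readr::write_tsv(fit$groups, file.path(outdir, "survival_groups.tsv"))
    readr::write_tsv(fit$km, file.path(outdir, "survival_km.tsv"))
    writeLines(sprintf("log-rank chi-square = %.6g on 1 df, p = %.6g",
                       fit$statistic, fit$p),
               file.path(outdir, "logrank_report.txt"))
    outputs <- c(outputs, "signature_scores.tsv", "survival_groups.tsv",
                 "survival_km.tsv", "logrank_report.txt")
  }
  list(signature = sig, fit = fit, outputs = outputs)
}

pipe_chromatin <- function(config, seed, outdir) {
  peaks <- read_peaks_bed(need_file(config, "peaks_bed", outdir, "peaks.bed"))
  pm_counts <- read_count_matrix(
    need_file(config, "peak_mtx", outdir, "peaks.mtx"),
    need_file(config, "peak_ids", outdir, "peak_ids.tsv"),
    need_file(config, "peak_cells", outdir, "peak_cells.tsv"),
    need_file(config, "peak_meta", outdir, "peak_meta.tsv")
  )
  pm <- peak_matrix(pm_counts$counts, peaks, pm_counts$cell_ids, pm_counts$cell_meta)
  genes <- gene_model(readr::read_tsv(need_file(config, "genes_tsv", outdir,
                                                "gene_models.tsv"),
                                      show_col_types = FALSE))
  meta <- pm$cell_meta
  mutant <- config$mutant_samples %||%
    unique(meta$sample_id[meta$group_label %in% "mutant"])
  control <- config$control_samples %||%
    setdiff(unique(meta$sample_id), mutant)
  cnv_values <- NULL
  if (!is.null(config$cnv_tsv) || file.exists(file.path(outdir, "cnv_values.tsv"))) {
    cv <- readr::read_tsv(need_file(config, "cnv_tsv", outdir, "cnv_values.tsv"),
                          show_col_types = FALSE)
    cnv_values <- as.matrix(cv[-1])
    rownames(cnv_values) <- cv$peak_id
  }
  dacrs <- dacr_consensus(pm, mutant, control, cnv_values = cnv_values,
                          p_cut = config$p_cut %||% 0.05,
                          min_frac = config$min_frac %||% 0.5)
  readr::write_tsv(dacrs, file.path(outdir, "dacr_result.tsv"))
  hit_peaks <- pm$peaks[dacrs$final_pass, , drop = FALSE]
  write_peaks_bed(hit_peaks, file.path(outdir, "dacrs.bed"))
  seqs <- read_fasta(need_file(config, "fasta", outdir, "peaks.fasta"))
  pwms <- read_jaspar_pfm(need_file(config, "pfm", outdir, "motifs.pfm"))
  hits <- scan_motifs(pwms, seqs[hit_peaks$peak_id],
                      p_threshold = config$p_threshold %||% 5e-5)
  readr::write_tsv(hits, file.path(outdir, "motif_hits.tsv"))
  coaccess <- if (!is.null(config$coaccess)) {
    read_coaccessibility(need_file(config, "coaccess"))
  } else NULL
  edges <- map_motifs_to_genes(
    hit_peaks, genes, hits,
    motif_lengths = vapply(pwms, function(p) ncol(p$matrix), integer(1)),
    coaccess = coaccess
  )
  readr::write_tsv(edges, file.path(outdir, "motif_gene_edges.tsv"))
  list(dacrs = dacrs, hits = hits, edges = edges,
       outputs = c("dacr_result.tsv", "dacrs.bed", "motif_hits.tsv",
                   "motif_gene_edges.tsv"))
}

pipe_cnv <- function(config, seed, outdir) {
  segs <- read_segments(need_file(config, "segments", outdir, "segments.tsv"))
  arm_map <- if (!is.null(config$arm_map) ||
                 file.exists(file.path(outdir, "arm_map.tsv"))) {
    readr::read_tsv(need_file(config, "arm_map", outdir, "arm_map.tsv"),
                    show_col_types = FALSE)
  } else NULL
  gain <- config$gain %||% 0.2
  loss <- config$loss %||% -0.2
  calls <- call_segments(segs, gain, loss)
  arms <- arm_weighted(segs, arm_map, gain, loss)
  readr::write_tsv(calls, file.path(outdir, "segment_calls.tsv"))
  readr::write_tsv(arms, file.path(outdir, "arm_calls.tsv"))
  list(segments = calls, arms = arms,
       outputs = c("segment_calls.tsv", "arm_calls.tsv"))
}

pipe_report <- function(config, seed, outdir) {
  manifests <- config$manifests %||%
    list.files(outdir, pattern = "^manifest_.*\\.json$", full.names = TRUE)
  lines <- unlist(lapply(manifests, function(m) {
    j <- read_json(m)
    sprintf("%s: seed %s, outputs: %s", j$subcommand, j$seed,
            paste(unlist(j$outputs), collapse = ", "))
  }))
  writeLines(lines %||% character(), file.path(outdir, "run_report.txt"))
  list(outputs = "run_report.txt")
}
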