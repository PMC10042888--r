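#' Configuration for the synthetic multi-omic cohort generator
#'
#' Defines the study conditions the generator emulates: a multi-sample
#' negative-binomial single-nucleus cohort with labeled cell types and tumor
#' subclusters, planted tumor-specific markers, a matched chromatin layer
#' (gene activity, peak counts, peak sequences with planted motif instances),
#' a bulk expression/protein cohort with exponential survival tied to a
#' planted hazard, and per-sample copy-number segments on a toy genome of
#' 4 chromosomes x 2 arms x 10 Mb.
#'
#' Defaults are the conditions used throughout the package's validation
#' experiments: 12 tumor samples (plus 2 normal adjacent tissue samples),
#' 2000 genes, 50 planted tumor markers at log2 fold change 1.5 present in
#' all samples, NB counts with log-normal(0, 0.3) cell size factors, a
#' 5000-peak layer with 100 planted less-accessible peaks (log2 fold change
#' -1) in a 4-sample mutant group vs 8 controls, and exponential survival
#' with hazard ratio 3 per standard-deviation of the planted signature.
#'
#' @param seed integer master seed; each generator draws from a named
#'   substream derived from it, so layers are reproducible independently.
#' @param n_tumor_samples,n_nat_samples cohort sizes.
#' @param cells_per_sample_by_type named integer vector of cells per tumor
#'   sample (must include `Tumor` and `PT`).
#' @param nat_cells_by_type named integer vector of cells per NAT sample.
#' @param n_genes number of genes.
#' @param nb_mean median NB base mean per gene (gene means are
#'   log-normal around it, sdlog 1).
#' @param nb_dispersion NB size parameter (variance = mu + mu^2/size).
#' @param size_factor_sdlog sdlog of per-cell log-normal size factors.
#' @param n_type_markers,type_marker_log2fc per-type identity genes and their
#'   elevation, giving cell types separable expression profiles.
#' @param n_planted_markers,marker_log2fc,marker_fraction planted
#'   tumor-specific markers: count, log2 fold change in tumor cells, and the
#'   fraction of tumor samples carrying the effect.
#' @param n_subclusters tumor subclusters per sample.
#' @param n_program_genes,program_log2fc,program_cluster planted expression
#'   program: gene count, effect, and the per-sample target subcluster index
#'   (0 disables the program).
#' @param n_peaks,peak_nb_mean,atac_cells_per_sample chromatin layer sizes.
#' @param n_mutant_samples leading samples assigned to the mutant group.
#' @param n_planted_dacrs,dacr_log2fc,dacr_direction,dacr_fraction planted
#'   differential peaks in mutant tumor cells (`direction` one of `"down"`,
#'   `"up"`, `"flip"`; `"flip"` alternates sign across mutant samples).
#' @param n_cnv_peaks,cnv_peak_log2cr peaks whose accessibility shift is
#'   driven by a planted copy-number change (used to exercise CNV correction).
#' @param motif_consensus named character vector of motif consensus sequences
#'   to embed; `n_motif_peaks` peaks carry each.
#' @param n_decoy_motifs additional random motifs with no planted instances.
#' @param n_motif_peaks peaks per planted motif.
#' @param n_bulk_tumor,n_bulk_nat bulk cohort sizes.
#' @param bulk_shift_log2 tumor-vs-NAT bulk shift for planted markers.
#' @param signature_genes genes carrying the survival signature (default: the
#'   first 20 planted markers).
#' @param signature_beta expression units added per latent score unit.
#' @param baseline_rate,hazard_log_hr exponential survival baseline rate and
#'   log hazard ratio per standardized latent signature score.
#' @param censor_max uniform censoring window upper bound.
#' @param segments_per_arm CNV segments per arm per sample.
#' @param planted_arm_cnvs tibble (`arm`, `log2cr`, `fraction`) of planted
#'   arm-level events (fraction of tumor samples carrying each).
#' @param segment_noise_sd sd of segment-level log2 copy-ratio noise
#'   (truncated at +/- 0.05).
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(
    seed = 1L,
    n_tumor_samples = 12L, n_nat_samples = 2L,
    cells_per_sample_by_type = c(Tumor = 200L, PT = 100L, Immune = 100L, Endothelial = 100L),
    nat_cells_by_type = c(PT = 150L, Immune = 50L, Endothelial = 50L),
    n_genes = 2000L, nb_mean = 0.5, nb_dispersion = 2,
    size_factor_sdlog = 0.3,
    n_type_markers = 60L, type_marker_log2fc = 2,
    n_planted_markers = 50L, marker_log2fc = 1.5, marker_fraction = 1,
    n_subclusters = 3L,
    n_program_genes = 30L, program_log2fc = 1, program_cluster = 2L,
    n_peaks = 5000L, peak_nb_mean = 1.0,
    atac_cells_per_sample = c(Tumor = 200L, PT = 50L),
    n_mutant_samples = 4L,
    n_planted_dacrs = 100L, dacr_log2fc = -1, dacr_direction = "down",
    dacr_fraction = 1,
    n_cnv_peaks = 0L, cnv_peak_log2cr = 1,
    motif_consensus = c(M_AP1 = "TGACGTCA", M_EBOX = "CACGTGAC"),
    n_decoy_motifs = 3L, n_motif_peaks = 50L,
    n_bulk_tumor = 80L, n_bulk_nat = 20L, bulk_shift_log2 = 1,
    signature_genes = NULL, signature_beta = 1,
    baseline_rate = 0.1, hazard_log_hr = log(3), censor_max = 20,
    segments_per_arm = 4L,
    planted_arm_cnvs = tibble(arm = "chr1q", log2cr = 0.4, fraction = 0.5),
    segment_noise_sd = 0.015) {
  stopifnot(nb_mean > 0, nb_dispersion > 0, n_genes >= 1)
  stopifnot(marker_fraction > 0, marker_fraction <= 1,
            dacr_fraction > 0, dacr_fraction <= 1)
  stopifnot(all(is.finite(c(marker_log2fc, dacr_log2fc, program_log2fc))))
  if (!all(c("Tumor", "PT") %in% names(cells_per_sample_by_type)) ||
      any(cells_per_sample_by_type[c("Tumor", "PT")] == 0)) {
    abort("tumor samples need Tumor and PT cells", class = "nephromics_config_error")
  }
  cfg <- as.list(environment())
  class(cfg) <- "cohort_config"
  cfg
}

# Named substreams off the master seed; keeps every derived seed < 2^31.
substream <- function(seed, name) {
  offs <- c(sn = 11L, atac = 23L, bulk = 37L, segments = 51L, genes = 67L)
  (as.integer(seed) %% 1000000L) * 1009L + offs[[name]]
}

sample_ids <- function(cfg) sprintf("T%02d", seq_len(cfg$n_tumor_samples))
nat_ids <- function(cfg) sprintf("NAT%d", seq_len(cfg$n_nat_samples))
gene_ids_of <- function(cfg) sprintf("g%04d", seq_len(cfg$n_genes))

# Gene index blocks: type-identity markers at the tail, planted tumor markers
# and program genes at the head (disjoint). Tumor cells carry no identity
# block of their own — their distinguishing genes are the planted markers —
# so a null cohort has no built-in tumor-specific genes.
gene_plan <- function(cfg) {
  genes <- gene_ids_of(cfg)
  types <- setdiff(names(cfg$cells_per_sample_by_type), "Tumor")
  n_tail <- cfg$n_type_markers * length(types)
  stopifnot(cfg$n_planted_markers + cfg$n_program_genes + n_tail <= cfg$n_genes)
  type_markers <- split(
    tail(genes, n_tail),
    rep(types, each = cfg$n_type_markers)
  )
  markers <- head(genes, cfg$n_planted_markers)
  program <- genes[cfg$n_planted_markers + seq_len(cfg$n_program_genes)]
  list(type_markers = type_markers, markers = markers, program = program)
}

#' Generate the synthetic single-nucleus cohort
#'
#' Negative-binomial genes-by-cells counts with per-cell log-normal size
#' factors. Cell types carry disjoint identity-gene blocks; planted tumor
#' markers have their mean multiplied by `2^marker_log2fc` in the tumor cells
#' of the leading `marker_fraction` of tumor samples; tumor cells carry
#' subcluster labels, with the planted program elevated in the target
#' subcluster. Fully deterministic under the config seed.
#'
#' @param config [cohort_config()].
#' @return list with `counts` ([sn_counts()]) and `truth` (list of tibbles:
#'   `markers`, `type_markers`, `programs`).
#' @export
gen_sn_cohort <- function(config) {
  cfg <- config
  plan <- gene_plan(cfg)
  genes <- gene_ids_of(cfg)
  withr::with_seed(substream(cfg$seed, "sn"), {
    base_mean <- rlnorm(cfg$n_genes, log(cfg$nb_mean), 1)
    names(base_mean) <- genes
    # planted markers and program genes emulate detectable genes (CA9-like):
    # base means drawn from the expressed range rather than the full log-normal
    mi <- match(c(plan$markers, plan$program), genes)
    base_mean[mi] <- rlnorm(length(mi), log(2 * cfg$nb_mean), 0.5)
    type_mult <- function(type) {
      m <- rep(1, cfg$n_genes)
      m[match(plan$type_markers[[type]], genes)] <- 2^cfg$type_marker_log2fc
      m
    }
    marker_samples <- head(sample_ids(cfg),
                           ceiling(cfg$marker_fraction * cfg$n_tumor_samples))
    marker_mult <- rep(1, cfg$n_genes)
    marker_mult[match(plan$markers, genes)] <- 2^cfg$marker_log2fc
    prog_mult <- rep(1, cfg$n_genes)
    prog_mult[match(plan$program, genes)] <- 2^cfg$program_log2fc

    blocks <- list()
    metas <- list()
    all_samples <- c(sample_ids(cfg), nat_ids(cfg))
    for (s in all_samples) {
      is_nat <- s %in% nat_ids(cfg)
      comp <- if (is_nat) cfg$nat_cells_by_type else cfg$cells_per_sample_by_type
      comp <- comp[comp > 0]
      for (ty in names(comp)) {
        n_c <- comp[[ty]]
        mu_g <- base_mean * type_mult(ty)
        if (ty == "Tumor" && s %in% marker_samples) mu_g <- mu_g * marker_mult
        if (ty == "Tumor") {
          sizes <- cell_split(n_c, cfg$n_subclusters)
          cl <- rep(sprintf("%s_c%d", s, seq_along(sizes)), sizes)
        } else {
          cl <- rep(NA_character_, n_c)
        }
        sf <- rlnorm(n_c, 0, cfg$size_factor_sdlog)
        mu <- outer(mu_g, sf)
        if (ty == "Tumor" && cfg$n_program_genes > 0 && cfg$program_cluster > 0) {
          target <- sprintf("%s_c%d", s, min(cfg$program_cluster, cfg$n_subclusters))
          hit <- which(cl == target)
          if (length(hit)) mu[, hit] <- mu[, hit] * prog_mult
        }
        cnt <- matrix(rnbinom(length(mu), mu = mu, size = cfg$nb_dispersion),
                      nrow = cfg$n_genes)
        blocks[[length(blocks) + 1L]] <- as(as(cnt, "CsparseMatrix"), "generalMatrix")
        metas[[length(metas) + 1L]] <- tibble(
          sample_id = s, cell_type = ty, cluster_id = cl,
          group_label = if (is_nat) "NAT" else "tumor"
        )
      }
    }
    counts <- do.call(cbind, blocks)
    meta <- dplyr::bind_rows(metas)
    cell_ids <- sprintf("%s_cell%05d", meta$sample_id,
                        stats::ave(seq_len(nrow(meta)), meta$sample_id, FUN = seq_along))
    sn <- sn_counts(counts, genes, cell_ids, meta)
    truth <- list(
      markers = tibble(gene = plan$markers, log2fc = cfg$marker_log2fc,
                       fraction_of_samples = cfg$marker_fraction,
                       samples = paste(marker_samples, collapse = ",")),
      type_markers = dplyr::bind_rows(lapply(names(plan$type_markers), function(ty) {
        tibble(gene = plan$type_markers[[ty]], cell_type = ty)
      })),
      programs = if (cfg$n_program_genes > 0 && cfg$program_cluster > 0) {
        tibble(gene = plan$program, log2fc = cfg$program_log2fc,
               target_cluster_index = min(cfg$program_cluster, cfg$n_subclusters))
      } else tibble(gene = character(), log2fc = numeric(),
                    target_cluster_index = integer())
    )
    list(counts = sn, truth = truth)
  })
}

cell_split <- function(n, k) {
  k <- max(1L, min(k, n))
  sizes <- rep(n %/% k, k)
  if (n %% k) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  sizes
}

#' Generate toy-genome gene models
#'
#' Tiles the configured genes across the 4 x 20 Mb toy genome with random
#' lengths (2-20 kb) and strands; coordinates are 1-based inclusive.
#'
#' @param config [cohort_config()].
#' @return gene-model tibble (see [gene_model()]).
#' @export
gen_gene_models <- function(config) {
  cfg <- config
  withr::with_seed(substream(cfg$seed, "genes"), {
    chroms <- sprintf("chr%d", 1:4)
    per_chrom <- cell_split(cfg$n_genes, 4L)
    rows <- purrr::map2_dfr(chroms, per_chrom, function(ch, n) {
      len <- round(runif(n, 2e3, 2e4))
      gap <- round(runif(n, 5e3, (2e7 - sum(len)) / max(n, 1) * 1.6))
      start <- cumsum(gap) + cumsum(dplyr::lag(len, default = 0)) + 1
      start <- pmin(start, 2e7 - len - 1)
      tibble(chrom = ch, strand = sample(c("+", "-"), n, replace = TRUE),
             start = start, end = start + len - 1)
    })
    rows$gene_id <- gene_ids_of(cfg)
    gene_model(rows[, c("gene_id", "chrom", "strand", "start", "end")])
  })
}

#' Toy genome arm map (4 chromosomes x 2 arms x 10 Mb)
#'
#' @return tibble with columns `chrom`, `arm`, `start`, `end` (0-based
#'   half-open, matching the segment convention).
#' @export
toy_arm_map <- function() {
  chroms <- sprintf("chr%d", 1:4)
  dplyr::bind_rows(
    tibble(chrom = chroms, arm = paste0(chroms, "p"), start = 0, end = 1e7),
    tibble(chrom = chroms, arm = paste0(chroms, "q"), start = 1e7, end = 2e7)
  ) |> dplyr::arrange(.data$chrom, .data$start)
}

#' Generate the synthetic chromatin (snATAC) layer
#'
#' Produces a gene-activity count matrix whose planted tumor markers carry an
#' accessibility fold above 1 in tumor cells, a peaks-by-cells fragment count
#' matrix with planted mutant-group differential peaks, per-cell FRiP, peak
#' sequences with planted motif instances at known offsets, the motif PWM set,
#' and per-peak/per-sample CNV values for the copy-number-driven peaks.
#'
#' @param config [cohort_config()].
#' @return list with `activity` ([sn_counts()]), `peaks` ([peak_matrix()]),
#'   `sequences` (named character), `pwms` (list of [pwm()]),
#'   `cnv_values` (peaks-by-samples matrix of log2 copy ratios), and `truth`.
#' @export
gen_atac_layer <- function(config) {
  cfg <- config
  plan <- gene_plan(cfg)
  genes <- gene_ids_of(cfg)
  withr::with_seed(substream(cfg$seed, "atac"), {
    samples <- sample_ids(cfg)
    mut_samples <- head(samples, cfg$n_mutant_samples)
    comp <- cfg$atac_cells_per_sample[cfg$atac_cells_per_sample > 0]

    # ---- gene activity: accessibility coupled to expression multipliers ----
    act_base <- rlnorm(cfg$n_genes, log(cfg$nb_mean), 1)
    act_base[match(plan$markers, genes)] <-
      rlnorm(length(plan$markers), log(2 * cfg$nb_mean), 0.5)
    act_marker <- rep(1, cfg$n_genes)
    act_marker[match(plan$markers, genes)] <- 2^(cfg$marker_log2fc / 2)
    blocks <- list(); metas <- list()
    for (s in samples) {
      for (ty in names(comp)) {
        n_c <- comp[[ty]]
        mu_g <- act_base
        if (ty == "Tumor") mu_g <- mu_g * act_marker
        m <- match(plan$type_markers[[ty]], genes)
        mu_g[m[!is.na(m)]] <- mu_g[m[!is.na(m)]] * 2^(cfg$type_marker_log2fc / 2)
        sf <- rlnorm(n_c, 0, cfg$size_factor_sdlog)
        cnt <- matrix(rnbinom(cfg$n_genes * n_c, mu = outer(mu_g, sf),
                              size = cfg$nb_dispersion), nrow = cfg$n_genes)
        blocks[[length(blocks) + 1L]] <- as(as(cnt, "CsparseMatrix"), "generalMatrix")
        metas[[length(metas) + 1L]] <- tibble(
          sample_id = rep(s, n_c), cell_type = ty,
          group_label = if (s %in% mut_samples) "mutant" else "nonmutant"
        )
      }
    }
    meta <- dplyr::bind_rows(metas)
    act_ids <- sprintf("%s_atac%05d", meta$sample_id,
                       stats::ave(seq_len(nrow(meta)), meta$sample_id, FUN = seq_along))
    activity <- sn_counts(do.call(cbind, blocks), genes, act_ids, meta)

    # ---- peaks on the toy genome ----
    n_pk <- cfg$n_peaks
    summit <- sample(500:(2e7 - 500), n_pk)  # unique positions: unique peak ids
    pk <- peak_table(tibble(
      chrom = sample(sprintf("chr%d", 1:4), n_pk, replace = TRUE),
      start = summit - 250, end = summit + 251, summit = summit,
      score = runif(n_pk, 2, 10)
    ))
    dacr_idx <- if (cfg$n_planted_dacrs > 0) seq_len(cfg$n_planted_dacrs) else integer()
    cnv_idx <- if (cfg$n_cnv_peaks > 0) {
      cfg$n_planted_dacrs + seq_len(cfg$n_cnv_peaks)
    } else integer()
    dacr_samples <- head(mut_samples, ceiling(cfg$dacr_fraction * length(mut_samples)))

    peak_base <- rlnorm(n_pk, log(cfg$peak_nb_mean), 0.6)
    # planted differential and CNV-driven peaks emulate reproducibly detected
    # peaks: base accessibility drawn from the well-covered range
    det <- c(dacr_idx, cnv_idx)
    if (length(det)) peak_base[det] <- rlnorm(length(det), log(2 * cfg$peak_nb_mean), 0.3)
    pblocks <- list()
    cnv_values <- matrix(0, n_pk, length(samples),
                         dimnames = list(pk$peak_id, samples))
    for (s in samples) {
      for (ty in names(comp)) {
        n_c <- comp[[ty]]
        mu_p <- peak_base
        if (ty == "Tumor" && s %in% dacr_samples && length(dacr_idx)) {
          sgn <- switch(cfg$dacr_direction,
            down = cfg$dacr_log2fc,
            up = abs(cfg$dacr_log2fc),
            flip = (if (match(s, mut_samples) %% 2 == 0) -1 else 1) * abs(cfg$dacr_log2fc)
          )
          mu_p[dacr_idx] <- mu_p[dacr_idx] * 2^sgn
        }
        if (ty == "Tumor" && s %in% mut_samples && length(cnv_idx)) {
          mu_p[cnv_idx] <- mu_p[cnv_idx] * 2^cfg$cnv_peak_log2cr
        }
        sf <- rlnorm(n_c, 0, cfg$size_factor_sdlog)
        cnt <- matrix(rnbinom(n_pk * n_c, mu = outer(mu_p, sf),
                              size = cfg$nb_dispersion), nrow = n_pk)
        pblocks[[length(pblocks) + 1L]] <- as(as(cnt, "CsparseMatrix"), "generalMatrix")
      }
      if (s %in% mut_samples && length(cnv_idx)) {
        cnv_values[cnv_idx, s] <- cfg$cnv_peak_log2cr
      }
    }
    pcounts <- do.call(cbind, pblocks)
    in_peak <- Matrix::colSums(pcounts)
    out_frag <- rnbinom(length(in_peak), mu = 0.6 * in_peak + 10, size = 20)
    meta$frip <- in_peak / pmax(in_peak + out_frag, 1)
    pm <- peak_matrix(pcounts, pk, act_ids, meta)

    # ---- peak sequences and motifs ----
    seqs <- vapply(seq_len(n_pk), function(i) {
      paste(sample(c("A", "C", "G", "T"), 501, replace = TRUE), collapse = "")
    }, character(1))
    names(seqs) <- pk$peak_id
    motif_truth <- list()
    motif_peak_pool <- setdiff(seq_len(n_pk), cnv_idx)
    for (k in seq_along(cfg$motif_consensus)) {
      mid <- names(cfg$motif_consensus)[k]
      cons <- cfg$motif_consensus[[k]]
      target <- motif_peak_pool[((k - 1) * cfg$n_motif_peaks) + seq_len(cfg$n_motif_peaks)]
      off <- sample.int(501 - nchar(cons), length(target), replace = TRUE)
      for (j in seq_along(target)) {
        i <- target[j]
        substr(seqs[i], off[j], off[j] + nchar(cons) - 1L) <- cons
      }
      motif_truth[[k]] <- tibble(motif_id = mid, peak_id = pk$peak_id[target],
                                 offset = off - 1L, strand = "+")
    }
    pwms <- lapply(seq_along(cfg$motif_consensus), function(k) {
      consensus_pwm(names(cfg$motif_consensus)[k], cfg$motif_consensus[[k]])
    })
    names(pwms) <- names(cfg$motif_consensus)
    for (d in seq_len(cfg$n_decoy_motifs)) {
      cons <- paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE), collapse = "")
      id <- sprintf("DECOY%d", d)
      pwms[[id]] <- consensus_pwm(id, cons)
    }

    truth <- list(
      dacrs = tibble(peak_id = pk$peak_id[dacr_idx],
                     direction = cfg$dacr_direction,
                     log2fc = cfg$dacr_log2fc,
                     samples = paste(dacr_samples, collapse = ",")),
      cnv_peaks = tibble(peak_id = pk$peak_id[cnv_idx],
                         log2cr = cfg$cnv_peak_log2cr),
      motifs = dplyr::bind_rows(motif_truth),
      mutant_samples = mut_samples,
      control_samples = setdiff(samples, mut_samples)
    )
    list(activity = activity, peaks = pm, sequences = seqs, pwms = pwms,
         cnv_values = cnv_values, truth = truth)
  })
}

consensus_pwm <- function(id, consensus, strength = 0.97) {
  bases <- c("A", "C", "G", "T")
  L <- nchar(consensus)
  m <- matrix((1 - strength) / 3, 4, L, dimnames = list(bases, NULL))
  hit <- match(strsplit(consensus, "")[[1]], bases)
  m[cbind(hit, seq_len(L))] <- strength
  pwm(m, id)
}

#' Generate the synthetic bulk cohort with survival
#'
#' Log2 FPKM expression with planted tumor-vs-NAT shifts for the tumor
#' markers, a protein layer sharing the shift (with some genes missing),
#' and exponential survival times for tumor samples whose log hazard is
#' `hazard_log_hr` times a standardized latent signature score; signature
#' genes' expression is coupled to the same latent score. Censoring is
#' independent uniform on `[0, censor_max]` (`censor_max = Inf` disables it).
#'
#' @param config [cohort_config()].
#' @return list with `cohort` ([bulk_cohort()]) and `truth` (tibble of latent
#'   scores per tumor sample, plus the signature gene list as an attribute).
#' @export
gen_bulk_survival <- function(config) {
  cfg <- config
  plan <- gene_plan(cfg)
  genes <- gene_ids_of(cfg)
  sig_genes <- cfg$signature_genes %||% head(plan$markers, min(20L, length(plan$markers)))
  withr::with_seed(substream(cfg$seed, "bulk"), {
    n_t <- cfg$n_bulk_tumor; n_n <- cfg$n_bulk_nat
    ids <- c(sprintf("BT%03d", seq_len(n_t)), sprintf("BN%03d", seq_len(n_n)))
    tissue <- rep(c("tumor", "NAT"), c(n_t, n_n))
    base <- rnorm(cfg$n_genes, 5, 1.5)
    expr <- matrix(rnorm(cfg$n_genes * (n_t + n_n), base, 0.7),
                   nrow = cfg$n_genes, dimnames = list(genes, ids))
    mi <- match(plan$markers, genes)
    expr[mi, tissue == "tumor"] <- expr[mi, tissue == "tumor"] + cfg$bulk_shift_log2
    z <- rnorm(n_t)
    si <- match(sig_genes, genes)
    expr[si, tissue == "tumor"] <- expr[si, tissue == "tumor"] +
      cfg$signature_beta * rep(z, each = length(si))
    keep_prot <- sort(sample.int(cfg$n_genes, round(0.9 * cfg$n_genes)))
    protein <- expr[keep_prot, , drop = FALSE] +
      matrix(rnorm(length(keep_prot) * (n_t + n_n), 0, 0.3), length(keep_prot))
    rate <- cfg$baseline_rate * exp(cfg$hazard_log_hr * z)
    t_ev <- rexp(n_t, rate)
    t_cn <- if (is.finite(cfg$censor_max)) runif(n_t, 0, cfg$censor_max) else rep(Inf, n_t)
    clinical <- tibble(
      sample_id = ids, tissue = tissue,
      stage = c(sample(c("I", "II", "III", "IV"), n_t, replace = TRUE,
                       prob = c(0.3, 0.2, 0.3, 0.2)), rep(NA, n_n)),
      mutation_group = NA_character_,
      surv_time = c(pmin(t_ev, t_cn), rep(NA, n_n)),
      event = c(as.numeric(t_ev <= t_cn), rep(NA, n_n))
    )
    truth <- tibble(sample_id = ids[tissue == "tumor"], latent_score = z)
    attr(truth, "signature_genes") <- sig_genes
    list(cohort = bulk_cohort(expr, clinical, protein), truth = truth)
  })
}

#' Generate per-sample copy-number segments on the toy genome
#'
#' Each arm is split into `segments_per_arm` contiguous segments; planted
#' arm-level events shift every segment of the arm by the stated log2 copy
#' ratio in the leading fraction of tumor samples. Segment noise is truncated
#' normal with |noise| <= 0.05.
#'
#' @param config [cohort_config()].
#' @return list with `segments` (see [segment_table()]) and `truth`.
#' @export
gen_segments <- function(config) {
  cfg <- config
  arms <- toy_arm_map()
  samples <- sample_ids(cfg)
  withr::with_seed(substream(cfg$seed, "segments"), {
    planted <- cfg$planted_arm_cnvs
    truth <- purrr::map_dfr(seq_len(nrow(planted)), function(i) {
      carriers <- head(samples, ceiling(planted$fraction[i] * length(samples)))
      tibble(sample_id = carriers, arm = planted$arm[i], log2cr = planted$log2cr[i])
    })
    segs <- purrr::map_dfr(samples, function(s) {
      purrr::map_dfr(seq_len(nrow(arms)), function(a) {
        k <- cfg$segments_per_arm
        cuts <- sort(round(runif(k - 1, arms$start[a], arms$end[a])))
        bounds <- unique(c(arms$start[a], cuts, arms$end[a]))
        shift <- truth$log2cr[truth$sample_id == s & truth$arm == arms$arm[a]]
        base <- if (length(shift)) shift[1] else 0
        noise <- pmax(pmin(rnorm(length(bounds) - 1, 0, cfg$segment_noise_sd), 0.05), -0.05)
        tibble(sample_id = s, chrom = arms$chrom[a],
               start = head(bounds, -1), end = tail(bounds, -1),
               log2cr = base + noise, arm = arms$arm[a])
      })
    })
    list(segments = segment_table(segs), truth = truth)
  })
}
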