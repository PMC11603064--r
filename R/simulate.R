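#' Simulation configuration for an allelic-series snRNA-seq dataset
#'
#' Builds and validates the parameter set for [simulate_dataset()]. The
#' defaults describe the world the package is validated against: 2,000 genes,
#' three genotype doses (0 = knockout, 1 = heterozygote, 2 = wild type) with
#' three biological replicates each and 500 nuclei per replicate, a latent
#' differentiation pseudotime on \[0, 1\], dose-sensitive repressed genes
#' (de-repressed by 0.5 log2 units per lost allele, so already visible in
#' Hets), threshold-like activated genes (down 1.0 log2 units in KO but only
#' 0.2 of that in Hets), a maturation lag of 0.1 pseudotime units per lost
#' allele, 200 dynamic genes whose expression peak is delayed by +0.2
#' pseudotime in mutants, cell-cycle programs restricted to early
#' (progenitor) pseudotime, and mitochondrial genes carrying the reserved
#' `mt-` prefix at ~0.5% of each cell's reads.
#'
#' Library sizes are log-normal with median 3,000 UMIs (sdlog 0.3), in the
#' range typical of droplet/combinatorial snRNA-seq; per-gene NB dispersions
#' are log-normal with median 0.1 (sdlog 0.5), the usual single-cell scale.
#'
#' @param n_genes number of genes.
#' @param n_cells_per_sample nuclei per biological replicate.
#' @param samples_per_dose named integer vector, replicates per dose; names
#'   are doses (`"0"`, `"1"`, `"2"`).
#' @param doses integer subset of `c(0, 1, 2)` to simulate.
#' @param frac_repressed,frac_activated,frac_dynamic,frac_cellcycle,frac_mito
#'   gene-class fractions; the remainder are null (flat, dose-insensitive)
#'   genes. Must sum to at most 1.
#' @param effect_repressed_log2fc_per_lost_allele log2 up-shift of repressed
#'   genes per lost allele (linear in dose).
#' @param effect_activated_log2fc_KO log2 down-shift of activated genes at
#'   dose 0.
#' @param het_activated_attenuation fraction of the KO effect expressed at
#'   dose 1 (threshold-like behaviour when small).
#' @param maturation_lag pseudotime lag per lost allele; mutant cells read
#'   out all pseudotime-dependent programs at
#'   `max(0, t - maturation_lag * (2 - dose))`.
#' @param n_timing_shifted number of dynamic genes whose Gaussian peak moves
#'   `timing_shift` later in mutant cells (Het and KO equally).
#' @param timing_shift size of that peak delay, pseudotime units.
#' @param dispersion_shape `c(meanlog, sdlog)` of the log-normal per-gene NB
#'   dispersion.
#' @param libsize_lognormal `c(meanlog, sdlog)` of the log-normal per-cell
#'   library size.
#' @param n_segments number of equal pseudotime segments used as cell-type
#'   labels.
#' @param n_tfs,targets_per_tf planted regulons: TFs drawn from unshifted
#'   dynamic genes, targets drawn from dynamic genes peaking nearby.
#' @param seed integer seed making the whole draw reproducible.
#' @return validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000L,
                       n_cells_per_sample = 500L,
                       samples_per_dose = c(`0` = 3L, `1` = 3L, `2` = 3L),
                       doses = c(0L, 1L, 2L),
                       frac_repressed = 0.05,
                       frac_activated = 0.05,
                       frac_dynamic = 0.30,
                       frac_cellcycle = 0.05,
                       frac_mito = 0.02,
                       effect_repressed_log2fc_per_lost_allele = 0.5,
                       effect_activated_log2fc_KO = 1.0,
                       het_activated_attenuation = 0.2,
                       maturation_lag = 0.1,
                       n_timing_shifted = 200L,
                       timing_shift = 0.2,
                       dispersion_shape = c(meanlog = log(0.1), sdlog = 0.5),
                       libsize_lognormal = c(meanlog = log(3000), sdlog = 0.3),
                       n_segments = 5L,
                       n_tfs = 5L,
                       targets_per_tf = 20L,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_cells_per_sample = as.integer(n_cells_per_sample),
    samples_per_dose = samples_per_dose,
    doses = sort(as.integer(doses)),
    frac_repressed = frac_repressed, frac_activated = frac_activated,
    frac_dynamic = frac_dynamic, frac_cellcycle = frac_cellcycle,
    frac_mito = frac_mito,
    effect_repressed_log2fc_per_lost_allele = effect_repressed_log2fc_per_lost_allele,
    effect_activated_log2fc_KO = effect_activated_log2fc_KO,
    het_activated_attenuation = het_activated_attenuation,
    maturation_lag = maturation_lag,
    n_timing_shifted = as.integer(n_timing_shifted),
    timing_shift = timing_shift,
    dispersion_shape = dispersion_shape,
    libsize_lognormal = libsize_lognormal,
    n_segments = as.integer(n_segments),
    n_tfs = as.integer(n_tfs), targets_per_tf = as.integer(targets_per_tf),
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  fr <- c(cfg$frac_repressed, cfg$frac_activated, cfg$frac_dynamic,
          cfg$frac_cellcycle, cfg$frac_mito)
  if (any(fr < 0) || any(fr > 1)) stopf("gene-class fractions must lie in [0, 1]")
  if (sum(fr) > 1) stopf("gene-class fractions sum to %.3f > 1", sum(fr))
  if (cfg$n_genes <= 0 || cfg$n_cells_per_sample <= 0)
    stopf("n_genes and n_cells_per_sample must be positive")
  if (!all(cfg$doses %in% 0:2)) stopf("doses must be a subset of {0, 1, 2}")
  if (!length(cfg$doses)) stopf("at least one dose required")
  for (d in cfg$doses) {
    ns <- cfg$samples_per_dose[[as.character(d)]]
    if (is.null(ns) || ns < 1) stopf("dose %d has no samples", d)
  }
  ## an archetype advertised as carrying an effect must own at least one gene
  n_rep <- round(cfg$frac_repressed * cfg$n_genes)
  n_act <- round(cfg$frac_activated * cfg$n_genes)
  n_dyn <- round(cfg$frac_dynamic * cfg$n_genes)
  if (cfg$frac_repressed > 0 && n_rep == 0 &&
      cfg$effect_repressed_log2fc_per_lost_allele > 0)
    stopf("frac_repressed rounds to 0 genes but its effect is nonzero")
  if (cfg$frac_activated > 0 && n_act == 0 && cfg$effect_activated_log2fc_KO > 0)
    stopf("frac_activated rounds to 0 genes but its effect is nonzero")
  if (cfg$n_timing_shifted > n_dyn && cfg$timing_shift > 0)
    stopf("n_timing_shifted (%d) exceeds the number of dynamic genes (%d)",
          cfg$n_timing_shifted, n_dyn)
  cfg
}

## Archetype response curves over pseudotime t in [0, 1]. All curves carry a
## 0.2 floor so no planted gene is ever fully off (keeps NB means sane).
curve_progenitor <- function(t) 0.2 + 1 / (1 + exp((t - 0.5) / 0.1))
curve_maturation <- function(t) 0.2 + 1 / (1 + exp(-(t - 0.5) / 0.1))
curve_bump       <- function(t, peak, width = 0.08)
  0.2 + exp(-(t - peak)^2 / (2 * width^2))

#' Simulate a multi-genotype snRNA-seq dataset with known ground truth
#'
#' Draws nuclei along a latent differentiation pseudotime and genes from a
#' small set of archetypes (progenitor-program repressed genes, maturation-
#' program activated genes, Gaussian-bump dynamic genes, cell-cycle S/G2M
#' programs, mitochondrial genes, flat null genes), then samples counts as
#' `NB(mean = libsize * p, dispersion alpha_g)` where `p` is the cell-wise
#' normalized expected expression. Dose effects multiply gene means:
#' repressed genes by `2^(effect * (2 - d))`; activated genes by
#' `2^(-effect)` at dose 0 and `2^(-effect * attenuation)` at dose 1.
#' Mutant cells read all pseudotime curves at an effective pseudotime shifted
#' earlier by `maturation_lag * (2 - d)` (truncated at 0), and timing-shifted
#' dynamic genes additionally peak `timing_shift` later in mutants. A 2-D
#' embedding (`emb1`, `emb2`) consistent with effective pseudotime is
#' attached to the cell table so trajectory and mixing statistics can run
#' without a clustering step.
#'
#' @param config a [sim_config()].
#' @return list with `counts` (sparse cells x genes integer matrix), `cells`
#'   (data.frame: cell, sample, dose, cluster, emb1, emb2), and `truth` (list
#'   with per-gene classes/effects, per-cell latent states, and planted
#'   regulons).
#' @export
simulate_dataset <- function(config = sim_config()) {
  cfg <- validate_sim_config(config)
  set.seed(cfg$seed)

  n_mito <- round(cfg$frac_mito * cfg$n_genes)
  n_rep  <- round(cfg$frac_repressed * cfg$n_genes)
  n_act  <- round(cfg$frac_activated * cfg$n_genes)
  n_dyn  <- round(cfg$frac_dynamic * cfg$n_genes)
  n_cc   <- round(cfg$frac_cellcycle * cfg$n_genes)
  n_ccS  <- n_cc %/% 2
  n_ccG  <- n_cc - n_ccS
  n_null <- cfg$n_genes - n_mito - n_rep - n_act - n_dyn - n_cc
  if (n_null < 0) stopf("gene-class counts exceed n_genes")

  gene_class <- c(rep("mito", n_mito), rep("repressed", n_rep),
                  rep("activated", n_act), rep("dynamic-neutral", n_dyn),
                  rep("cellcycle-S", n_ccS), rep("cellcycle-G2M", n_ccG),
                  rep("null", n_null))
  gene <- character(cfg$n_genes)
  gene[gene_class == "mito"] <- sprintf("mt-%d", seq_len(n_mito))
  gene[gene_class != "mito"] <- sprintf("g%04d", seq_len(cfg$n_genes - n_mito))

  baseline <- rlnorm(cfg$n_genes, 0, 1)
  peak <- rep(NA_real_, cfg$n_genes)
  dyn_idx <- which(gene_class == "dynamic-neutral")
  peak[dyn_idx] <- runif(n_dyn)
  timing_shift <- rep(0, cfg$n_genes)
  if (cfg$n_timing_shifted > 0 && cfg$timing_shift != 0 && n_dyn > 0) {
    shifted <- sample(dyn_idx, min(cfg$n_timing_shifted, n_dyn))
    timing_shift[shifted] <- cfg$timing_shift
  }
  alpha <- rlnorm(cfg$n_genes, cfg$dispersion_shape[["meanlog"]],
                  cfg$dispersion_shape[["sdlog"]])

  eff_rep <- cfg$effect_repressed_log2fc_per_lost_allele
  eff_act <- cfg$effect_activated_log2fc_KO
  att <- cfg$het_activated_attenuation
  dose_log2fc <- function(d) {
    lfc <- numeric(cfg$n_genes)
    lfc[gene_class == "repressed"] <- eff_rep * (2 - d)
    if (d == 0) lfc[gene_class == "activated"] <- -eff_act
    if (d == 1) lfc[gene_class == "activated"] <- -eff_act * att
    lfc
  }

  seg_breaks <- seq(0, 1, length.out = cfg$n_segments + 1)
  seg_label <- function(t) paste0("seg", findInterval(t, seg_breaks,
                                                      rightmost.closed = TRUE))

  blocks <- list(); cell_rows <- list(); bi <- 0L
  for (d in cfg$doses) {
    for (s in seq_len(cfg$samples_per_dose[[as.character(d)]])) {
      nc <- cfg$n_cells_per_sample
      sample_id <- sprintf("d%d_s%d", d, s)
      t_true <- runif(nc)
      t_eff <- pmax(0, t_true - cfg$maturation_lag * (2 - d))
      lib <- rlnorm(nc, cfg$libsize_lognormal[["meanlog"]],
                    cfg$libsize_lognormal[["sdlog"]])
      cycling <- t_true < 0.3
      phase <- ifelse(cycling, sample(c("S", "G2M"), nc, replace = TRUE), "G1/G0")

      ## relative expression r[g, c]: archetype curve x baseline x dose factor
      r <- matrix(0, cfg$n_genes, nc)
      for (cls in unique(gene_class)) {
        gi <- which(gene_class == cls)
        if (!length(gi)) next
        ## dose-class genes ride TRUE pseudotime: the maturation lag must not
        ## leak into their planted log2 fold changes (the lag is expressed
        ## through cell positions and the dynamic program instead)
        r[gi, ] <- switch(cls,
          "repressed" = outer(baseline[gi], curve_progenitor(t_true)),
          "activated" = outer(baseline[gi], curve_maturation(t_true)),
          "dynamic-neutral" = {
            pk <- outer(peak[gi], rep(1, nc)) +
              if (d < 2) matrix(timing_shift[gi], length(gi), nc) else 0
            tm <- matrix(t_eff, length(gi), nc, byrow = TRUE)
            baseline[gi] * curve_bump(tm, pk)
          },
          "cellcycle-S" = outer(baseline[gi], 0.2 + 2.5 * (phase == "S")),
          "cellcycle-G2M" = outer(baseline[gi], 0.2 + 2.5 * (phase == "G2M")),
          outer(baseline[gi], rep(1, nc)))  # null and mito: flat
      }
      r <- r * 2^dose_log2fc(d)
      ## pin mitochondrial reads at ~0.5% of each cell's transcriptome
      mi <- which(gene_class == "mito")
      if (length(mi)) {
        nonmito <- colSums(r[-mi, , drop = FALSE])
        r[mi, ] <- outer(baseline[mi] / sum(baseline[mi]),
                         nonmito * 0.005 / 0.995)
      }
      p <- sweep(r, 2, colSums(r), "/")
      mu <- sweep(p, 2, lib, "*")
      y <- matrix(rnbinom(length(mu), mu = mu, size = rep(1 / alpha, nc)),
                  cfg$n_genes, nc)
      dimnames(y) <- list(gene, sprintf("%s_c%03d", sample_id, seq_len(nc)))
      bi <- bi + 1L
      nz <- which(y != 0)                 # triplets: cheaper than rbind of
      blocks[[bi]] <- list(               # per-sample sparse blocks
        cell = ((nz - 1L) %/% cfg$n_genes) + 1L,
        gene = ((nz - 1L) %% cfg$n_genes) + 1L,
        x = y[nz], cell_names = colnames(y))
      cell_rows[[bi]] <- data.frame(
        cell = colnames(y), sample = sample_id, dose = d,
        true_pseudotime = t_true, eff_pseudotime = t_eff,
        true_type = seg_label(t_true), phase = phase, libsize = lib,
        stringsAsFactors = FALSE)
    }
  }
  offsets <- cumsum(c(0L, vapply(blocks, function(b) length(b$cell_names),
                                 integer(1))))
  counts <- Matrix::sparseMatrix(
    i = unlist(lapply(seq_along(blocks),
                      function(k) blocks[[k]]$cell + offsets[k])),
    j = unlist(lapply(blocks, `[[`, "gene")),
    x = unlist(lapply(blocks, `[[`, "x")),
    dims = c(offsets[length(offsets)], cfg$n_genes),
    dimnames = list(unlist(lapply(blocks, `[[`, "cell_names")), gene))
  cell_truth <- do.call(rbind, cell_rows)
  rownames(cell_truth) <- NULL

  ## embedding: noisy 1-D manifold in effective pseudotime (what an observed
  ## expression embedding would recover), genotypes interleaved along it
  emb1 <- cell_truth$eff_pseudotime + rnorm(nrow(cell_truth), 0, 0.01)
  emb2 <- rnorm(nrow(cell_truth), 0, 0.02)

  ## planted regulons: TFs from unshifted dynamic genes; targets peak nearby
  ## a regulon's "active segment" is only well-defined when the TF's target
  ## window (peak +/- 0.1) sits inside one segment, so TFs are drawn from
  ## dynamic genes peaking near a segment center
  regulons <- list()
  centers <- (seq_len(cfg$n_segments) - 0.5) / cfg$n_segments
  near_center <- vapply(peak, function(p)
    !is.na(p) && min(abs(p - centers)) < 0.04, logical(1))
  tf_pool <- dyn_idx[timing_shift[dyn_idx] == 0 & near_center[dyn_idx]]
  if (cfg$n_tfs > 0 && length(tf_pool) > cfg$n_tfs) {
    tfs <- sample(tf_pool, cfg$n_tfs)
    for (tf in tfs) {
      near <- dyn_idx[abs(peak[dyn_idx] - peak[tf]) < 0.1 & dyn_idx != tf]
      tgt <- if (length(near) > cfg$targets_per_tf)
        sample(near, cfg$targets_per_tf) else near
      seg <- seg_label(min(max(peak[tf], 0), 1 - 1e-9))
      regulons[[gene[tf]]] <- structure(gene[tgt], active_segment = seg)
    }
  }

  lfc_by_dose <- sapply(c(0, 1, 2), dose_log2fc)
  colnames(lfc_by_dose) <- c("lfc_dose0", "lfc_dose1", "lfc_dose2")
  if (!all(c(0, 1, 2) %in% cfg$doses))                 # no shift without the dose
    lfc_by_dose[, !(c(0, 1, 2) %in% cfg$doses)] <- NA_real_

  gene_truth <- data.frame(gene = gene, class = gene_class,
                           peak_time = peak, timing_shift = timing_shift,
                           baseline = baseline, dispersion = alpha,
                           lfc_by_dose, stringsAsFactors = FALSE)

  cells <- data.frame(cell = cell_truth$cell, sample = cell_truth$sample,
                      dose = cell_truth$dose, cluster = cell_truth$true_type,
                      emb1 = emb1, emb2 = emb2, stringsAsFactors = FALSE)
  list(counts = counts, cells = cells,
       truth = list(genes = gene_truth, cells = cell_truth,
                    regulons = regulons, config = cfg))
}

#' Simulate a null dataset (no genotype effect of any kind)
#'
#' Same generative process as [simulate_dataset()] with every genotype effect
#' forced to zero: no repressed or activated genes, no maturation lag, no
#' timing shift. Genotype labels are exchangeable by construction, which is
#' what the type-I-error and permutation-calibration suites require.
#'
#' @param config a [sim_config()]; its effect fields are overridden.
#' @return as [simulate_dataset()].
#' @export
simulate_null_dataset <- function(config = sim_config()) {
  cfg <- validate_sim_config(config)
  cfg$frac_repressed <- 0
  cfg$frac_activated <- 0
  cfg$effect_repressed_log2fc_per_lost_allele <- 0
  cfg$effect_activated_log2fc_KO <- 0
  cfg$maturation_lag <- 0
  cfg$n_timing_shifted <- 0L
  cfg$timing_shift <- 0
  simulate_dataset(cfg)
}
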