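#' DEG burden by repeated fixed-size downsampling
#'
#' Cluster size drives DE sensitivity, so raw per-cluster DEG counts are not
#' comparable. For each cluster whose genotype arms can support it, a
#' balanced draw of `n_cells` nuclei (ceiling(n_cells / 2) per arm, without
#' replacement) is taken, the full pseudobulk Wald DE between the two doses
#' is run on the subsample, and called DEGs are counted; this repeats `reps`
#' times. The burden is the mean count over reps. Each cluster's rep counts
#' are compared against the pooled rep counts of all other eligible clusters
#' with a two-sided Mann-Whitney U test, BH-adjusted across clusters.
#' Clusters whose arms cannot supply the draw are flagged `N/A` (never
#' reported as zero burden). Each cluster uses its own PRNG stream keyed by
#' `(seed, cluster)` so adding clusters does not perturb the others' draws.
#'
#' @param counts cells x genes count matrix.
#' @param cells cell table with `cluster`, `sample`, `dose`.
#' @param doses length-2 dose contrast, reference first (default `c(2, 0)`).
#' @param n_cells downsampling size per cluster (default 700).
#' @param reps number of repetitions (default 10).
#' @param seed base seed.
#' @param lfc_min,fdr DEG calling thresholds (defaults 0.2, 0.05).
#' @return data.frame: cluster, n_arm_min, eligible, burden (mean DEGs),
#'   burden_per_cell, rep counts (comma-joined), U statistic, p, q.
#' @export
deg_burden <- function(counts, cells, doses = c(2, 0), n_cells = 700,
                       reps = 10, seed = 1, lfc_min = 0.2, fdr = 0.05) {
  counts <- assert_counts(counts)
  assert_cells(cells, counts, need = c("cell", "sample", "cluster"))
  per_arm <- ceiling(n_cells / 2)
  clusters <- sort(unique(cells$cluster))
  rep_counts <- list()
  arm_min <- integer(length(clusters)); names(arm_min) <- clusters

  for (cl in clusters) {
    sel <- cells$cluster == cl & cells$dose %in% doses
    idx1 <- which(sel & cells$dose == doses[1])
    idx2 <- which(sel & cells$dose == doses[2])
    arm_min[cl] <- min(length(idx1), length(idx2))
    if (arm_min[cl] < per_arm) next
    set.seed(stream_seed(seed, cl))
    cnt <- integer(reps)
    for (r in seq_len(reps)) {
      take <- c(sample(idx1, per_arm), sample(idx2, per_arm))
      sub_cells <- cells[take, , drop = FALSE]
      sub_cells$cluster <- cl
      pb <- aggregate_pseudobulk(counts[take, , drop = FALSE], sub_cells)
      res <- tryCatch(call_degs(wald_pairwise(pb, doses), lfc_min, fdr),
                      error = function(e) NULL)
      cnt[r] <- if (is.null(res)) NA_integer_ else sum(res$called, na.rm = TRUE)
    }
    rep_counts[[cl]] <- cnt
  }

  eligible <- names(rep_counts)
  out <- data.frame(cluster = clusters, n_arm_min = arm_min[clusters],
                    eligible = clusters %in% eligible,
                    burden = NA_real_, burden_per_cell = NA_real_,
                    reps = NA_character_, U = NA_real_, p = NA_real_,
                    row.names = NULL, stringsAsFactors = FALSE)
  for (cl in eligible) {
    i <- match(cl, out$cluster)
    cnt <- rep_counts[[cl]]
    out$burden[i] <- mean(cnt, na.rm = TRUE)
    out$burden_per_cell[i] <- out$burden[i] / n_cells
    out$reps[i] <- paste(cnt, collapse = ",")
    others <- unlist(rep_counts[setdiff(eligible, cl)], use.names = FALSE)
    if (length(others)) {
      wt <- suppressWarnings(wilcox.test(cnt, others, exact = FALSE))
      out$U[i] <- unname(wt$statistic); out$p[i] <- wt$p.value
    }
  }
  out$q <- NA_real_
  if (length(eligible) > 1) {
    fam <- out$eligible
    out$q[fam] <- bh_adjust(out$p[fam])
  }
  out
}
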