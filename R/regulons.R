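#' AUCell-style regulon activity scores
#'
#' Per cell, genes are ranked by decreasing count (ties broken by a seeded
#' uniform jitter below 1e-9 of the count scale, recorded in the run log by
#' the pipeline) and each regulon is scored by the area under its recovery
#' curve within the top `ceiling(top_frac * G)` ranks, normalized so a set
#' lying entirely inside the window scores 1 and a set entirely outside
#' scores 0. Regulons with no detected genes yield a column of `NA`;
#' regulons with fewer than 5 genes present are flagged in
#' `attr(, "small_regulons")`.
#'
#' @param counts cells x genes count matrix (any monotone transform gives
#'   identical scores — the statistic is rank-based).
#' @param regulons named list of target-gene vectors (set name = TF).
#' @param top_frac top-expression window (default 0.05).
#' @param seed jitter seed.
#' @return cells x regulons matrix of AUC scores in \[0, 1\].
#' @export
aucell_scores <- function(counts, regulons, top_frac = 0.05, seed = 1) {
  counts <- assert_counts(counts)
  G <- ncol(counts)
  w <- ceiling(top_frac * G)
  sets <- lapply(regulons, function(s) match(intersect(s, colnames(counts)),
                                             colnames(counts)))
  small <- names(sets)[vapply(sets, length, integer(1)) < 5]
  ## max achievable area for a set of size m: hits occupy ranks 1..min(m, w)
  max_area <- function(m) { mm <- min(m, w); sum(pmin(seq_len(w), mm)) }
  set.seed(seed)
  A <- matrix(NA_real_, nrow(counts), length(sets),
              dimnames = list(rownames(counts), names(sets)))
  scale <- max(counts@x, 1)
  for (i in seq_len(nrow(counts))) {
    x <- as.numeric(counts[i, ]) + runif(G, 0, 1e-10 * scale)
    rk <- integer(G)
    rk[order(-x)] <- seq_len(G)
    for (j in seq_along(sets)) {
      si <- sets[[j]]
      if (!length(si)) next
      r <- sort(rk[si])
      r <- r[r <= w]
      ## area under the step recovery curve over ranks 1..w
      area <- if (length(r)) sum(w - r + 1) else 0
      A[i, j] <- area / max_area(length(si))
    }
  }
  attr(A, "top_frac") <- top_frac
  attr(A, "window") <- w
  attr(A, "small_regulons") <- small
  A
}

#' Regulon specificity scores (RSS)
#'
#' For each regulon and cluster: normalize the cell-wise activity vector to
#' sum 1 (`P`) and the cluster indicator to sum 1 (`Q`); `RSS = 1 -
#' JSD(P, Q)` with the Jensen-Shannon divergence in log base 2, so both JSD
#' and RSS lie in \[0, 1\]. RSS is 1 exactly when activity is proportional
#' to the cluster indicator; all-zero (or all-`NA`) activity gives missing
#' RSS.
#'
#' @param activity cells x regulons AUC matrix ([aucell_scores()]).
#' @param clusters cluster label per cell.
#' @return regulons x clusters RSS matrix.
#' @export
regulon_specificity <- function(activity, clusters) {
  clusters <- as.character(clusters)
  if (length(unique(clusters)) < 2) stopf("need at least 2 clusters")
  cls <- sort(unique(clusters))
  out <- matrix(NA_real_, ncol(activity), length(cls),
                dimnames = list(colnames(activity), cls))
  for (j in seq_len(ncol(activity))) {
    a <- activity[, j]
    if (anyNA(a) || sum(a) == 0) next
    P <- a / sum(a)
    for (ci in seq_along(cls)) {
      ind <- as.numeric(clusters == cls[ci])
      Q <- ind / sum(ind)
      out[j, ci] <- 1 - js_divergence(P, Q)
    }
  }
  out
}

## Jensen-Shannon divergence, log base 2 (0 log 0 := 0)
js_divergence <- function(P, Q) {
  M <- (P + Q) / 2
  kl2 <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  0.5 * kl2(P, M) + 0.5 * kl2(Q, M)
}

#' Differential regulon activity between genotypes within clusters
#'
#' Two-sided Wilcoxon rank-sum test on per-cell AUC scores between two dose
#' arms, per (regulon, cluster), with BH across all tests performed. A
#' result is flagged when `q < 0.05` and the mean AUC difference is at least
#' `min_delta`. (regulon, cluster) pairs with an arm under `min_cells` are
#' skipped.
#'
#' @param activity cells x regulons AUC matrix.
#' @param cells cell table with `cluster` and `dose`.
#' @param arms length-2 dose vector, reference first (default `c(2, 0)`).
#' @param min_cells minimum cells per arm (default 20).
#' @param min_delta effect-size floor on `|mean AUC difference|` (default 0.01).
#' @return data.frame: regulon, cluster, delta_auc (alt minus ref), p, q,
#'   flagged.
#' @export
differential_regulons <- function(activity, cells, arms = c(2, 0),
                                  min_cells = 20, min_delta = 0.01) {
  rows <- list()
  for (cl in sort(unique(cells$cluster))) {
    i_ref <- which(cells$cluster == cl & cells$dose == arms[1])
    i_alt <- which(cells$cluster == cl & cells$dose == arms[2])
    if (length(i_ref) < min_cells || length(i_alt) < min_cells) next
    for (j in seq_len(ncol(activity))) {
      a <- activity[i_ref, j]; b <- activity[i_alt, j]
      if (anyNA(a) || anyNA(b)) next
      wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE))
      p <- wt$p.value
      if (is.nan(p)) p <- 1       # identical constant arms
      rows[[length(rows) + 1L]] <- data.frame(
        regulon = colnames(activity)[j], cluster = cl,
        delta_auc = mean(b) - mean(a), p = p, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(regulon = character(), cluster = character(),
                      delta_auc = numeric(), p = numeric(), q = numeric(),
                      flagged = logical()))
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$flagged <- out$q < 0.05 & abs(out$delta_auc) >= min_delta
  out
}

#' Cell-type-specific regulons by the max-RSS MAD rule
#'
#' Convention for the denominator of "x out of y regulons differential": a
#' regulon is *specific* when its maximum RSS across clusters exceeds the
#' across-regulon median of maxima by at least `n_mad` median absolute
#' deviations.
#'
#' @param rss regulons x clusters RSS matrix.
#' @param n_mad MAD multiplier (default 2).
#' @return character vector of specific regulon names.
#' @export
specific_regulons <- function(rss, n_mad = 2) {
  mx <- apply(rss, 1, max, na.rm = TRUE)
  mx <- mx[is.finite(mx)]
  thr <- median(mx) + n_mad * stats::mad(mx)
  names(mx)[mx > thr]
}
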