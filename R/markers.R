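#' Cluster marker detection (one-vs-rest Wilcoxon)
#'
#' For each cluster versus all other cells, genes are pre-filtered to
#' `log2FC >= logfc_thresh` (difference of mean log2 normalized expression)
#' and `max(pct.1, pct.2) >= min_pct`, then tested with the two-sided
#' Wilcoxon rank-sum test (normal approximation with tie correction).
#' `pct.1`/`pct.2` are the detection fractions (expression > 0) inside and
#' outside the cluster. BH adjustment is applied within each cluster.
#' Clusters with fewer than 3 cells are skipped with a warning.
#'
#' @param norm cells x genes normalized matrix.
#' @param clusters cluster label per cell.
#' @param logfc_thresh minimum log2 fold change (default 0.5).
#' @param min_pct minimum detection fraction in either group (default 0.25).
#' @return data.frame: gene, cluster, log2fc, pct_1, pct_2, statistic (the
#'   rank-sum U for the cluster group), p, q.
#' @export
find_markers <- function(norm, clusters, logfc_thresh = 0.5, min_pct = 0.25) {
  clusters <- as.character(clusters)
  if (length(unique(clusters)) < 2) stopf("need at least 2 clusters")
  out <- list()
  for (cl in unique(clusters)) {
    inc <- clusters == cl
    if (sum(inc) < 3) { warnf("cluster '%s' has <3 cells; skipped", cl); next }
    m1 <- Matrix::colSums(norm[inc, , drop = FALSE]) / sum(inc)
    m2 <- Matrix::colSums(norm[!inc, , drop = FALSE]) / sum(!inc)
    pct1 <- Matrix::colSums(norm[inc, , drop = FALSE] > 0) / sum(inc)
    pct2 <- Matrix::colSums(norm[!inc, , drop = FALSE] > 0) / sum(!inc)
    lfc <- m1 - m2                       # already log2 units
    test <- which(lfc >= logfc_thresh & pmax(pct1, pct2) >= min_pct)
    if (!length(test)) next
    res <- vapply(test, function(j) {
      x <- norm[inc, j]; y <- norm[!inc, j]
      wt <- suppressWarnings(
        wilcox.test(as.numeric(x), as.numeric(y), exact = FALSE, correct = FALSE))
      c(wt$statistic, wt$p.value)
    }, numeric(2))
    out[[cl]] <- data.frame(gene = colnames(norm)[test], cluster = cl,
                            log2fc = lfc[test], pct_1 = pct1[test],
                            pct_2 = pct2[test], statistic = res[1, ],
                            p = res[2, ], q = bh_adjust(res[2, ]),
                            row.names = NULL, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(gene = character(), cluster = character(),
                      log2fc = numeric(), pct_1 = numeric(), pct_2 = numeric(),
                      statistic = numeric(), p = numeric(), q = numeric()))
  do.call(rbind, c(out, make.row.names = FALSE))
}
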