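#' Aggregate single-cell counts into pseudobulk samples
#'
#' Sums counts over all cells sharing a (cluster, sample) combination.
#' Combinations with zero cells are omitted. The result is gene-major
#' (genes x pseudobulk columns), the orientation bulk count models expect.
#'
#' @param counts cells x genes count matrix.
#' @param cells cell table with `cluster` and `sample` (and optionally
#'   `dose` and other sample covariates, carried into the column metadata).
#' @return list: `counts` (genes x combinations integer matrix), `coldata`
#'   (data.frame: cluster, sample, n_cells, plus sample-level covariates).
#' @export
aggregate_pseudobulk <- function(counts, cells) {
  counts <- assert_counts(counts)
  assert_cells(cells, counts, need = c("cell", "sample", "cluster"))
  combo <- factor(paste(cells$cluster, cells$sample, sep = "|"))
  G <- Matrix::sparseMatrix(i = seq_len(nrow(counts)),
                            j = as.integer(combo), x = 1,
                            dims = c(nrow(counts), nlevels(combo)))
  pb <- Matrix::t(counts) %*% G
  pb <- as.matrix(pb)
  colnames(pb) <- levels(combo)
  parts <- do.call(rbind, strsplit(levels(combo), "|", fixed = TRUE))
  coldata <- data.frame(cluster = parts[, 1], sample = parts[, 2],
                        n_cells = as.integer(table(combo)[levels(combo)]),
                        stringsAsFactors = FALSE)
  ## sample-level covariates (constant within sample) travel along
  for (cv in intersect(c("dose", "age", "sex"), names(cells))) {
    map <- tapply(cells[[cv]], cells$sample, function(x) x[1])
    coldata[[cv]] <- as.vector(map[coldata$sample])
  }
  rownames(coldata) <- colnames(pb)
  list(counts = pb, coldata = coldata)
}

#' Median-of-ratios size factors
#'
#' For each pseudobulk column, the size factor is the median across
#' all-nonzero genes of the ratio of the gene's count to its geometric mean
#' across columns, rescaled so the factors' geometric mean is 1.
#'
#' @param pb_counts genes x columns integer matrix.
#' @return numeric vector of positive size factors, one per column.
#' @export
estimate_size_factors <- function(pb_counts) {
  pb_counts <- as.matrix(pb_counts)
  pos <- rowSums(pb_counts > 0) == ncol(pb_counts)
  if (!any(pos))
    stopf("no gene has nonzero counts in every column; consider a positive-counts-only fallback")
  loggeo <- rowMeans(log(pb_counts[pos, , drop = FALSE]))
  s <- apply(log(pb_counts[pos, , drop = FALSE]) - loggeo, 2,
             function(lr) exp(median(lr)))
  s / geo_mean(s)
}

#' Gene-wise NB dispersion estimation
#'
#' Three stages, mirroring the standard bulk workflow without its
#' empirical-Bayes machinery: (1) method-of-moments initialisation; (2)
#' profile-likelihood maximisation of the NB likelihood in the dispersion
#' alone, holding the fitted means fixed at `mean_g * s_j` (evaluated on a
#' log-spaced grid with quadratic interpolation at the optimum — fast and
#' accurate to a few percent, which the downstream shrinkage dominates
#' anyway); (3) shrinkage of `log(alpha)` halfway toward a mean-dispersion
#' trend that is log-linear in 1/mean. Dispersions are floored at 1e-8;
#' all-zero genes get `NA` and are excluded from testing.
#'
#' @param pb_counts genes x columns integer matrix.
#' @param size_factors per-column size factors.
#' @param shrink_weight weight on the gene-wise MLE in the log-scale convex
#'   combination with the trend (default 0.5).
#' @return numeric vector of dispersions (`NA` for all-zero genes), with the
#'   unshrunk MLEs and trend values as attributes.
#' @export
estimate_dispersions <- function(pb_counts, size_factors, shrink_weight = 0.5) {
  Y <- as.matrix(pb_counts)
  if (ncol(Y) < 2) stopf("need at least 2 pseudobulk columns")
  floor_a <- 1e-8
  norm <- sweep(Y, 2, size_factors, "/")
  m <- rowMeans(norm)
  ok <- m > 0
  MU <- outer(m, size_factors)

  grid <- exp(seq(log(floor_a), log(10), length.out = 48))
  L <- matrix(-Inf, nrow(Y), length(grid))
  Yok <- Y[ok, , drop = FALSE]; MUok <- MU[ok, , drop = FALSE]
  for (j in seq_along(grid))
    L[ok, j] <- rowSums(dnbinom(Yok, size = 1 / grid[j], mu = MUok, log = TRUE))
  best <- max.col(L, ties.method = "first")
  la <- log(grid)
  alpha_mle <- rep(NA_real_, nrow(Y))
  for (i in which(ok)) {
    b <- best[i]
    if (b == 1 || b == length(grid)) { alpha_mle[i] <- grid[b]; next }
    ## quadratic interpolation through the three bracketing grid points
    x <- la[(b - 1):(b + 1)]; yv <- L[i, (b - 1):(b + 1)]
    denom <- (x[1] - x[2]) * (x[1] - x[3]) * (x[2] - x[3])
    A <- (x[3] * (yv[2] - yv[1]) + x[2] * (yv[1] - yv[3]) + x[1] * (yv[3] - yv[2])) / denom
    B <- (x[3]^2 * (yv[1] - yv[2]) + x[2]^2 * (yv[3] - yv[1]) + x[1]^2 * (yv[2] - yv[3])) / denom
    alpha_mle[i] <- if (A < 0) exp(-B / (2 * A)) else grid[b]
  }
  alpha_mle <- pmax(alpha_mle, floor_a)

  ## mean-dispersion trend: log(alpha) ~ a + b / mean; fit away from the floor
  fit_ok <- ok & alpha_mle > 2 * floor_a
  alpha_trend <- rep(NA_real_, nrow(Y))
  if (sum(fit_ok) >= 10) {
    tr <- lm(log(alpha_mle[fit_ok]) ~ I(1 / m[fit_ok]))
    alpha_trend[ok] <- exp(cbind(1, 1 / m[ok]) %*% coef(tr))[, 1]
  } else {
    alpha_trend[ok] <- exp(median(log(alpha_mle[ok])))
  }
  alpha <- rep(NA_real_, nrow(Y))
  alpha[ok] <- pmax(exp(shrink_weight * log(alpha_mle[ok]) +
                        (1 - shrink_weight) * log(alpha_trend[ok])), floor_a)
  structure(alpha, mle = alpha_mle, trend = alpha_trend,
            names = rownames(Y))
}
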