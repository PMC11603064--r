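#' Root-anchored graph pseudotime
#'
#' Builds a symmetric k-nearest-neighbour graph on the embedding (Euclidean
#' edge weights) and assigns each cell the shortest-path geodesic distance
#' from the root cell, min-max scaled to \[0, 1\]. Cells unreachable from the
#' root get `NA` pseudotime and a warning; downstream operations exclude
#' them. Deterministic given the embedding.
#'
#' @param embedding cells x dimensions numeric matrix with rownames (cell
#'   ids).
#' @param root cell id (or row index) anchoring pseudotime 0; typically the
#'   most immature cell, chosen by the analyst.
#' @param k neighbours per cell (default 15).
#' @return list of class `trajectory_model`: `pseudotime` (named vector),
#'   `graph` (igraph), `weights` (sparse symmetric adjacency for
#'   autocorrelation tests), `root`.
#' @export
assign_pseudotime <- function(embedding, root, k = 15) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  ids <- rownames(embedding) %||% as.character(seq_len(n))
  rownames(embedding) <- ids
  if (is.character(root)) {
    root_i <- match(root, ids)
    if (is.na(root_i)) stopf("root cell '%s' not found", root)
  } else root_i <- as.integer(root)

  nn <- knn_index(embedding, min(k, n - 1))
  ii <- rep(seq_len(n), each = ncol(nn$idx))
  jj <- as.vector(t(nn$idx))
  dd <- sqrt(pmax(as.vector(t(nn$dist2)), 0))
  ## symmetrise: keep an edge if it appears in either direction
  A <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(dd, dd),
                            dims = c(n, n), use.last.ij = TRUE)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE)
  d <- igraph::distances(g, v = root_i, weights = igraph::E(g)$weight)[1, ]
  unreachable <- !is.finite(d)
  if (any(unreachable))
    warnf("%d cell(s) unreachable from the root; pseudotime set to NA",
          sum(unreachable))
  pt <- d
  pt[unreachable] <- NA
  rng <- range(pt, na.rm = TRUE)
  pt <- if (diff(rng) > 0) (pt - rng[1]) / diff(rng) else pt - rng[1]
  names(pt) <- ids
  W <- A
  W@x[W@x > 0] <- 1                   # unweighted symmetric adjacency
  structure(list(pseudotime = pt, graph = g, weights = W, root = ids[root_i]),
            class = "trajectory_model")
}

#' Moran's I test for pseudotemporal dynamic genes
#'
#' For each gene, `I = (N/W) * (z' A z) / (z' z)` on the trajectory's
#' symmetric neighbour graph, with a one-sided (positive autocorrelation)
#' p-value from the randomization-assumption normal approximation. Genes
#' with BH `q < 0.05` are flagged dynamic. Constant genes get missing
#' statistics and `dynamic = FALSE`.
#'
#' @param norm cells x genes normalized matrix.
#' @param model a [assign_pseudotime()] result (its `weights` are used) or a
#'   symmetric sparse weight matrix.
#' @param fdr dynamic-gene threshold (default 0.05).
#' @return data.frame: gene, moran_i, expected_i, z, p, q, dynamic.
#' @export
morans_i_test <- function(norm, model, fdr = 0.05) {
  W <- if (inherits(model, "trajectory_model")) model$weights else model
  n <- nrow(norm)
  if (nrow(W) != n) stopf("weight matrix does not match the expression matrix")
  Z <- as.matrix(norm)
  Z <- sweep(Z, 2, colMeans(Z))
  s0 <- sum(W)
  WZ <- as.matrix(W %*% Z)
  m2 <- colSums(Z^2)
  constant <- m2 == 0
  I <- rep(NA_real_, ncol(Z))
  I[!constant] <- (n / s0) * colSums(Z * WZ)[!constant] / m2[!constant]

  ## randomization-assumption moments (gene-specific via kurtosis b2)
  rs <- Matrix::rowSums(W); cs <- Matrix::colSums(W)
  s1 <- sum((W + Matrix::t(W))@x^2) / 2
  s2 <- sum((rs + cs)^2)
  EI <- -1 / (n - 1)
  b2 <- rep(NA_real_, ncol(Z))
  b2[!constant] <- n * colSums(Z^4)[!constant] / (m2[!constant]^2)
  varI <- (n * ((n^2 - 3 * n + 3) * s1 - n * s2 + 3 * s0^2) -
           b2 * ((n^2 - n) * s1 - 2 * n * s2 + 6 * s0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * s0^2) - EI^2
  z <- (I - EI) / sqrt(varI)
  p <- pnorm(z, lower.tail = FALSE)
  q <- bh_adjust(p)
  data.frame(gene = colnames(norm), moran_i = I, expected_i = EI, z = z,
             p = p, q = q, dynamic = !is.na(q) & q < fdr,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Kolmogorov-Smirnov pseudotime shift tests per cluster
#'
#' Within each cluster, compares the pseudotime distributions of each
#' genotype pair with the two-sided two-sample KS test; BH adjustment spans
#' all (cluster, pair) tests performed. Arms with fewer than `min_cells`
#' cells (after dropping missing pseudotime) are skipped with a warning.
#'
#' @param pseudotime named vector (or vector aligned to `cells`).
#' @param cells cell table with `cluster` and `dose`.
#' @param pairs list of length-2 dose vectors, reference first (default
#'   WT-vs-Het and WT-vs-KO).
#' @param min_cells minimum cells per arm (default 20).
#' @return data.frame: cluster, dose_ref, dose_alt, n_ref, n_alt, D,
#'   median_shift (alt minus ref medians), p, q.
#' @export
ks_shift_test <- function(pseudotime, cells,
                          pairs = list(c(2, 1), c(2, 0)), min_cells = 20) {
  rows <- list()
  for (cl in sort(unique(cells$cluster))) {
    for (pr in pairs) {
      a <- pseudotime[cells$cluster == cl & cells$dose == pr[1]]
      b <- pseudotime[cells$cluster == cl & cells$dose == pr[2]]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (length(a) < min_cells || length(b) < min_cells) {
        warnf("cluster '%s' pair %d-%d skipped (<%d cells in an arm)",
              cl, pr[1], pr[2], min_cells)
        next
      }
      kt <- suppressWarnings(ks.test(a, b))
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, dose_ref = pr[1], dose_alt = pr[2],
        n_ref = length(a), n_alt = length(b),
        D = unname(kt$statistic), median_shift = median(b) - median(a),
        p = kt$p.value, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(cluster = character(), dose_ref = numeric(),
                      dose_alt = numeric(), n_ref = integer(),
                      n_alt = integer(), D = numeric(),
                      median_shift = numeric(), p = numeric(), q = numeric()))
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out
}

#' Relative pseudotime density difference versus wild type
#'
#' Bins pseudotime into `bins` equal-width bins on \[0, 1\] and reports, per
#' mutant genotype and bin, `(frac_mutant - frac_WT) / frac_WT`. Bins with
#' no WT mass are reported missing.
#'
#' @param pseudotime numeric vector.
#' @param dose genotype dose per cell.
#' @param bins number of bins (default 10).
#' @param ref reference dose (default 2 = WT).
#' @return data.frame: dose, bin, bin_mid, rel_diff.
#' @export
pseudotime_density_diff <- function(pseudotime, dose, bins = 10, ref = 2) {
  ok <- !is.na(pseudotime)
  pseudotime <- pseudotime[ok]; dose <- dose[ok]
  if (!any(dose == ref)) stopf("no cells with reference dose %s", ref)
  edges <- seq(0, 1, length.out = bins + 1)
  bin_of <- findInterval(pseudotime, edges, rightmost.closed = TRUE)
  frac <- function(d) tabulate(bin_of[dose == d], bins) / sum(dose == d)
  fw <- frac(ref)
  rows <- lapply(setdiff(sort(unique(dose)), ref), function(d) {
    fm <- frac(d)
    data.frame(dose = d, bin = seq_len(bins),
               bin_mid = (edges[-1] + edges[-(bins + 1)]) / 2,
               rel_diff = ifelse(fw > 0, (fm - fw) / fw, NA_real_))
  })
  do.call(rbind, rows)
}
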