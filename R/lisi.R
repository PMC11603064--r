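#' Local inverse Simpson's index (LISI) of label mixing
#'
#' For each cell, the `3 * perplexity` nearest neighbours (Euclidean, in the
#' supplied embedding) are weighted by a Gaussian kernel whose per-cell
#' bandwidth is calibrated by bisection so the neighbourhood entropy equals
#' `log(perplexity)` (tolerance 1e-5), as in the original LISI method. The
#' kernel weights are summed per label into probabilities `p_k`, and
#' `LISI = 1 / sum(p_k^2)`: the effective number of labels in the
#' neighbourhood, between 1 (unmixed) and the number of labels (perfectly
#' mixed).
#'
#' @param embedding numeric matrix, cells x dimensions.
#' @param labels character/factor vector per cell (e.g. genotype).
#' @param perplexity effective neighbourhood size (default 30).
#' @return numeric vector of per-cell LISI scores.
#' @export
compute_lisi <- function(embedding, labels, perplexity = 30) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  labels <- as.character(labels)
  if (length(labels) != n) stopf("labels length must match embedding rows")
  n_lab <- length(unique(labels))
  if (n < 2 || n_lab < 2) return(rep(1, n))
  k <- min(3 * perplexity, n - 1)
  if (n < 3 * perplexity)
    warnf("fewer than 3*perplexity cells; using k = %d neighbours", k)

  nn <- knn_index(embedding, k)
  out <- numeric(n)
  logU <- log(perplexity)
  lab_id <- as.integer(factor(labels))
  for (i in seq_len(n)) {
    d2 <- nn$dist2[i, ]
    beta <- calibrate_beta(d2, logU)
    w <- exp(-beta * d2)
    w <- w / sum(w)
    pk <- vapply(split(w, lab_id[nn$idx[i, ]]), sum, numeric(1))
    out[i] <- 1 / sum(pk^2)
  }
  out
}

## blockwise brute-force kNN (excluding self); returns indices and squared
## distances, cells x k
knn_index <- function(embedding, k, block = 512L) {
  n <- nrow(embedding)
  idx <- matrix(0L, n, k)
  d2 <- matrix(0, n, k)
  sq <- rowSums(embedding^2)
  for (start in seq(1, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    cross <- embedding[rows, , drop = FALSE] %*% t(embedding)
    dd <- outer(sq[rows], sq, "+") - 2 * cross
    for (j in seq_along(rows)) {
      i <- rows[j]
      di <- dd[j, ]
      di[i] <- Inf
      ord <- order(di)[seq_len(k)]
      idx[i, ] <- ord
      d2[i, ] <- pmax(di[ord], 0)
    }
  }
  list(idx = idx, dist2 = d2)
}

## bisection on the Gaussian precision so the neighbourhood entropy hits the
## target perplexity; mirrors the t-SNE/LISI calibration
calibrate_beta <- function(d2, logU, tol = 1e-5, max_iter = 100) {
  beta <- 1
  lo <- -Inf; hi <- Inf
  for (it in seq_len(max_iter)) {
    w <- exp(-beta * d2)
    sw <- sum(w)
    if (sw == 0) { H <- 0 } else {
      H <- log(sw) + beta * sum(d2 * w) / sw
    }
    diff <- H - logU
    if (abs(diff) < tol) break
    if (diff > 0) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
    else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
  }
  beta
}
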