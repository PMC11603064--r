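#' Cell-cycle phase scoring
#'
#' Module score per cell for the S and G2M programs: mean normalized
#' expression of the signature genes minus the mean of control genes drawn
#' from expression-matched bins (genes are binned by their dataset-average
#' expression into `n_bins` quantile bins; `n_ctrl` controls are sampled per
#' signature gene's bin, seeded). Phase is the argmax of the two scores when
#' either is positive, else `G1/G0`.
#'
#' @param norm cells x genes normalized matrix ([normalize_log()]).
#' @param s_genes,g2m_genes character vectors of signature genes; at least 5
#'   of each must be present in `norm`.
#' @param n_bins number of average-expression bins (default 25).
#' @param n_ctrl control genes sampled per bin per signature gene (default 50).
#' @param seed seed for control sampling.
#' @return data.frame: cell, s_score, g2m_score, phase.
#' @export
score_cell_cycle <- function(norm, s_genes, g2m_genes, n_bins = 25,
                             n_ctrl = 50, seed = 1) {
  genes <- colnames(norm)
  s_genes <- intersect(s_genes, genes)
  g2m_genes <- intersect(g2m_genes, genes)
  if (length(s_genes) < 5) stopf("fewer than 5 S-phase genes present in the matrix")
  if (length(g2m_genes) < 5) stopf("fewer than 5 G2M-phase genes present in the matrix")

  avg <- Matrix::colSums(norm) / nrow(norm)
  ## quantile bins on average expression; ties broken lexicographically
  ord <- order(avg, genes)
  bin <- integer(length(genes))
  bin[ord] <- ceiling(seq_along(ord) / (length(ord) / n_bins))
  names(bin) <- genes

  set.seed(seed)
  score_one <- function(sig) {
    ctrl <- unique(unlist(lapply(sig, function(g) {
      pool <- genes[bin == bin[[g]]]
      sample(pool, min(n_ctrl, length(pool)))
    })))
    sig_mean <- Matrix::rowSums(norm[, sig, drop = FALSE]) / length(sig)
    ctrl_mean <- Matrix::rowSums(norm[, ctrl, drop = FALSE]) / length(ctrl)
    as.numeric(sig_mean - ctrl_mean)
  }
  s <- score_one(s_genes)
  g2m <- score_one(g2m_genes)
  phase <- ifelse(s <= 0 & g2m <= 0, "G1/G0", ifelse(s > g2m, "S", "G2M"))
  data.frame(cell = rownames(norm), s_score = s, g2m_score = g2m,
             phase = phase, row.names = NULL, stringsAsFactors = FALSE)
}
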