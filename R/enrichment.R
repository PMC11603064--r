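#' Hypergeometric over-representation analysis
#'
#' One-sided upper-tail hypergeometric test (equivalently the one-sided
#' Fisher exact test on the 2x2 table) of each gene set against the query,
#' within the caller-supplied universe (all genes expressed in the relevant
#' cluster). Sets are intersected with the universe; sets overlapping the
#' query by fewer than `min_overlap` genes are omitted. BH across the
#' reported sets.
#'
#' @param query character vector of genes (must lie inside `universe`).
#' @param universe character vector of background genes.
#' @param sets a [read_gmt()]-style named list of gene vectors.
#' @param min_overlap minimum overlap to report a set (default 1).
#' @return data.frame: set, k (overlap), K (set size in universe), n (query
#'   size), N (universe size), fold (observed / expected), p, q, genes
#'   (comma-joined overlap).
#' @export
hypergeom_ora <- function(query, universe, sets, min_overlap = 1) {
  universe <- unique(universe)
  bad <- setdiff(query, universe)
  if (length(bad))
    stopf("query gene(s) outside the universe: %s",
          paste(utils::head(bad, 5), collapse = ", "))
  query <- unique(query)
  N <- length(universe); n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    set <- intersect(sets[[nm]], universe)
    K <- length(set)
    ov <- intersect(query, set)
    k <- length(ov)
    if (k < min_overlap) return(NULL)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N,
               fold = k / (n * K / N), p = p,
               genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(set = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), fold = numeric(),
                      p = numeric(), q = numeric(), genes = character()))
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out[, c("set", "k", "K", "n", "N", "fold", "p", "q", "genes")]
}

#' Expression-matched resampling enrichment
#'
#' Null model for the overlap of a query gene list with a target set when
#' the target has an expression bias: `B` draws of `draw_size` genes,
#' without replacement, from the top `top_frac` of the expression-ranked
#' gene list. Fold enrichment is the observed overlap divided by the
#' *median* null overlap; the empirical p-value is
#' `(1 + #\{null >= observed\}) / (1 + B)`.
#'
#' @param query character vector of genes (e.g. the DEGs).
#' @param ranked_genes character vector ranked by decreasing expression
#'   (ties already resolved by the caller; [rank_genes_by_expression()]
#'   breaks ties by gene label).
#' @param target target set (e.g. disorder-associated genes).
#' @param draw_size genes per draw (the study draws 900).
#' @param top_frac expressed-gene fraction forming the pool (default 0.5).
#' @param B number of draws (default 1000).
#' @param seed draw seed.
#' @return list: observed, null (length-B integer vector), median_null,
#'   fold (`NA` with a warning if the median null is 0), p, draw_size,
#'   pool_size.
#' @export
resample_enrichment <- function(query, ranked_genes, target, draw_size,
                                top_frac = 0.5, B = 1000, seed = 1) {
  pool <- ranked_genes[seq_len(floor(top_frac * length(ranked_genes)))]
  if (draw_size > length(pool))
    stopf("draw_size (%d) exceeds the pool size (%d)", draw_size, length(pool))
  if (!length(intersect(target, pool)))
    warnf("target set is disjoint from the expression pool")
  observed <- length(intersect(unique(query), target))
  in_target <- pool %in% target
  set.seed(seed)
  null <- vapply(seq_len(B), function(b)
    sum(in_target[sample.int(length(pool), draw_size)]), integer(1))
  med <- median(null)
  fold <- if (med == 0) { warnf("median null overlap is 0; fold undefined"); NA_real_ }
          else observed / med
  list(observed = observed, null = null, median_null = med, fold = fold,
       p = (1 + sum(null >= observed)) / (1 + B),
       draw_size = draw_size, pool_size = length(pool))
}

#' Rank genes by mean normalized expression (ties by gene label)
#' @param norm cells x genes normalized matrix.
#' @return character vector of genes, most expressed first.
#' @export
rank_genes_by_expression <- function(norm) {
  avg <- Matrix::colSums(norm) / nrow(norm)
  colnames(norm)[order(-avg, colnames(norm))]
}

#' Yates continuity-corrected chi-square test for a 2x2 table
#'
#' `chi2 = N (|ad - bc| - N/2)^2 / ((a+b)(c+d)(a+c)(b+d))`, clamped to 0
#' when `|ad - bc| <= N/2`; upper-tail chi-square p with 1 df. A zero margin
#' yields statistic 0, p = 1.
#'
#' @param table 2x2 non-negative count matrix.
#' @return list: statistic, df (= 1), p.
#' @export
chisq_yates <- function(table) {
  x <- as.matrix(table)
  if (!all(dim(x) == 2) || any(x < 0)) stopf("need a 2x2 table of non-negative counts")
  a <- x[1, 1]; b <- x[1, 2]; c <- x[2, 1]; d <- x[2, 2]
  N <- a + b + c + d
  if (N == 0) stopf("empty table")
  marg <- c(a + b, c + d, a + c, b + d)
  if (any(marg == 0)) return(list(statistic = 0, df = 1L, p = 1))
  delta <- abs(a * d - b * c)
  stat <- if (delta <= N / 2) 0 else N * (delta - N / 2)^2 / prod(marg)
  list(statistic = stat, df = 1L,
       p = if (stat == 0) 1 else pchisq(stat, 1, lower.tail = FALSE))
}

#' One-sided Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric tail via [stats::fisher.test()], reporting the
#' conditional MLE odds ratio. A zero margin yields p = 1.
#'
#' @param table 2x2 non-negative count matrix.
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @return list: odds_ratio, p.
#' @export
fisher_exact <- function(table, alternative = "greater") {
  x <- as.matrix(table)
  if (!all(dim(x) == 2) || any(x < 0)) stopf("need a 2x2 table of non-negative counts")
  if (any(c(rowSums(x), colSums(x)) == 0))
    return(list(odds_ratio = NA_real_, p = 1))
  ft <- fisher.test(x, alternative = alternative)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value)
}
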