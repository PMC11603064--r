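#' @importFrom Matrix rowSums colSums t Diagonal sparseMatrix readMM writeMM
#' @importFrom methods as is
#' @importFrom stats p.adjust median quantile rnbinom rlnorm runif rnorm rbinom
#'   pnorm pchisq pt pf phyper fisher.test ks.test wilcox.test optimize lm
#'   model.matrix coef var sd dnbinom setNames ecdf predict
#' @importFrom utils read.delim write.table packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin wrapper around [stats::p.adjust()] with `method = "BH"`; every
#' multiple-testing correction in the package goes through this so the
#' family-wise convention is stated in one place. `NA` p-values are kept `NA`
#' and do not count toward the family size.
#'
#' @param p numeric vector of p-values.
#' @return numeric vector of BH step-up adjusted p-values.
#' @export
bh_adjust <- function(p) p.adjust(p, method = "BH")

geo_mean <- function(x) exp(mean(log(x)))

## Deterministic 31-bit stream key from a base seed and a string label, so
## e.g. each cluster in deg_burden gets its own reproducible PRNG stream.
stream_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(as.character(label))) h <- (h * 31 + ch) %% 2147483647L
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

## counts matrices are cells x genes dgCMatrix with dimnames everywhere
assert_counts <- function(counts) {
  if (!methods::is(counts, "sparseMatrix")) counts <- methods::as(counts, "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("count matrix must carry cell (row) and gene (column) names")
  if (any(counts@x < 0) || any(counts@x != round(counts@x)))
    stopf("count matrix must contain non-negative integers")
  counts
}

assert_cells <- function(cells, counts = NULL, need = c("cell", "sample")) {
  miss <- setdiff(need, names(cells))
  if (length(miss))
    stopf("cell table is missing column(s): %s", paste(miss, collapse = ", "))
  if (!is.null(counts) && !identical(as.character(cells$cell), rownames(counts)))
    stopf("cell table rows must match count matrix rows (same cells, same order)")
  invisible(cells)
}
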