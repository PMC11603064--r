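#' Per-cell QC thresholds
#'
#' Defaults are the study-standard snRNA-seq cutoffs this package is built
#' around: 800-6000 UMIs, 300-3000 detected genes, at most 1% mitochondrial
#' reads, and `log(genes)/log(UMIs) >= 0.9` (cells below that ratio have
#' implausibly few genes for their depth — typically ambient/degraded
#' barcodes). The ratio is base-invariant.
#'
#' @param umi_min,umi_max UMI bounds (inclusive).
#' @param genes_min,genes_max detected-gene bounds (inclusive).
#' @param mito_pct_max maximum mitochondrial percentage (0-100 scale).
#' @param log_ratio_min minimum `log(genes)/log(UMIs)`.
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(umi_min = 800, umi_max = 6000,
                          genes_min = 300, genes_max = 3000,
                          mito_pct_max = 1.0, log_ratio_min = 0.9) {
  if (umi_min >= umi_max) stopf("umi_min must be < umi_max")
  if (genes_min >= genes_max) stopf("genes_min must be < genes_max")
  structure(list(umi_min = umi_min, umi_max = umi_max, genes_min = genes_min,
                 genes_max = genes_max, mito_pct_max = mito_pct_max,
                 log_ratio_min = log_ratio_min), class = "qc_thresholds")
}

#' Apply per-cell QC filters
#'
#' A cell is kept iff it satisfies every rule in `thr`; the report enumerates
#' all violated rules per cell (`umi-low`, `umi-high`, `genes-low`,
#' `genes-high`, `mito-high`, `log-ratio`, `zero-depth`). Mitochondrial genes
#' are recognised by the reserved `mt-` prefix (case-insensitive). Zero-depth
#' cells are dropped with reason `zero-depth`, never an error.
#'
#' @param counts cells x genes count matrix.
#' @param cells cell table aligned to `counts` rows.
#' @param thr a [qc_thresholds()].
#' @return list: `counts` and `cells` restricted to kept cells, and `qc`, the
#'   full per-cell report (umis, genes, mito_pct, log_ratio, keep, reasons).
#' @export
apply_qc_filters <- function(counts, cells, thr = qc_thresholds()) {
  counts <- assert_counts(counts)
  assert_cells(cells, counts, need = c("cell"))
  mito <- grepl("^mt-", colnames(counts), ignore.case = TRUE)
  umis <- Matrix::rowSums(counts)
  ngene <- Matrix::rowSums(counts > 0)
  mito_pct <- if (any(mito))
    100 * Matrix::rowSums(counts[, mito, drop = FALSE]) / pmax(umis, 1)
  else rep(0, nrow(counts))
  log_ratio <- ifelse(umis > 1, log(pmax(ngene, 1)) / log(umis), NA_real_)

  reasons <- vector("list", nrow(counts))
  add <- function(idx, tag) for (i in which(idx)) reasons[[i]] <<- c(reasons[[i]], tag)
  zero <- umis == 0
  add(zero, "zero-depth")
  add(!zero & umis < thr$umi_min, "umi-low")
  add(!zero & umis > thr$umi_max, "umi-high")
  add(!zero & ngene < thr$genes_min, "genes-low")
  add(!zero & ngene > thr$genes_max, "genes-high")
  add(!zero & mito_pct > thr$mito_pct_max, "mito-high")
  add(!zero & !is.na(log_ratio) & log_ratio < thr$log_ratio_min, "log-ratio")

  keep <- lengths(reasons) == 0
  qc <- data.frame(cell = rownames(counts), umis = umis, genes = ngene,
                   mito_pct = mito_pct, log_ratio = log_ratio, keep = keep,
                   reasons = vapply(reasons, function(r)
                     paste(r, collapse = ","), character(1)),
                   row.names = NULL, stringsAsFactors = FALSE)
  list(counts = counts[keep, , drop = FALSE],
       cells = cells[keep, , drop = FALSE], qc = qc)
}

#' Depth-normalize and log-transform counts
#'
#' `value = log2(1 + count / cell_total * scale)`. Sparsity is preserved
#' (zero iff the raw count is zero). The normalization record (scale factor,
#' log base) travels as attributes.
#'
#' @param counts cells x genes count matrix with no zero-depth cells.
#' @param scale scale factor (default 10,000).
#' @return sparse cells x genes matrix of log2 normalized expression.
#' @export
normalize_log <- function(counts, scale = 10000) {
  counts <- assert_counts(counts)
  tot <- Matrix::rowSums(counts)
  if (any(tot == 0))
    stopf("zero-depth cell(s) present (e.g. %s); run apply_qc_filters first",
          rownames(counts)[which(tot == 0)[1]])
  norm <- Matrix::Diagonal(x = scale / tot) %*% counts
  norm <- methods::as(norm, "CsparseMatrix")
  norm@x <- log2(1 + norm@x)
  dimnames(norm) <- dimnames(counts)
  attr(norm, "scale_factor") <- scale
  attr(norm, "log_base") <- 2
  norm
}
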