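#' Read a sparse count matrix from Matrix Market files
#'
#' Reads an `.mtx` file with sidecar gene and cell label files (one label per
#' line, first tab-separated field used). On disk the 10x convention is
#' assumed (genes are rows, cells are columns); internally everything is
#' cells x genes, so the matrix is transposed on the way in.
#'
#' @param mtx path to the Matrix Market file.
#' @param genes,cells paths to the row (gene) and column (cell) label files;
#'   default `<dir>/genes.tsv` and `<dir>/barcodes.tsv` next to `mtx`.
#' @return sparse integer matrix, cells x genes, fully labelled.
#' @export
read_counts_mtx <- function(mtx,
                            genes = file.path(dirname(mtx), "genes.tsv"),
                            cells = file.path(dirname(mtx), "barcodes.tsv")) {
  m <- Matrix::readMM(mtx)
  g <- read_labels(genes)
  b <- read_labels(cells)
  if (nrow(m) != length(g))
    stopf("MTX declares %d gene rows but %s has %d labels", nrow(m), genes, length(g))
  if (ncol(m) != length(b))
    stopf("MTX declares %d cell columns but %s has %d labels", ncol(m), cells, length(b))
  if (anyDuplicated(g)) stopf("duplicate gene identifiers in %s", genes)
  if (anyDuplicated(b)) stopf("duplicate cell identifiers in %s", cells)
  if (any(m@x != round(m@x))) stopf("MTX contains non-integer values")
  dimnames(m) <- list(g, b)
  assert_counts(Matrix::t(m))
}

read_labels <- function(path) {
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  as.character(x[[1]])
}

#' Write a count matrix as Matrix Market plus label sidecars
#'
#' Inverse of [read_counts_mtx()]: the internal cells x genes matrix is
#' written gene-major (genes as rows) with `genes.tsv` and `barcodes.tsv`.
#'
#' @param counts cells x genes sparse matrix.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(counts, dir) {
  counts <- assert_counts(counts)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::t(counts), file.path(dir, "matrix.mtx"))
  writeLines(colnames(counts), file.path(dir, "genes.tsv"))
  writeLines(rownames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a gene-set collection from a GMT file
#'
#' Tab-separated lines: set name, description, then gene identifiers.
#' Duplicate genes within a set are dropped with a warning; set order is
#' preserved.
#'
#' @param path GMT file path.
#' @return named list of character vectors with a `description` attribute on
#'   each set.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stopf("GMT line with fewer than 3 fields: %s", ln)
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      warnf("duplicate genes in set '%s' dropped", f[1])
      genes <- unique(genes)
    }
    sets[[f[1]]] <- structure(genes, description = f[2])
  }
  sets
}

#' Write a gene-set collection as GMT
#' @param sets named list of character vectors (optional `description` attr).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, attr(sets[[nm]], "description") %||% nm, sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) read.delim(path, stringsAsFactors = FALSE)

#' Write a simulation config as a flat key-value file
#' @param cfg a [sim_config()].
#' @param path output file.
#' @export
write_sim_config <- function(cfg, path) {
  flat <- unlist(cfg)
  writeLines(paste(names(flat), flat, sep = "\t"), path)
  invisible(path)
}

#' Write a simulated dataset (counts + cell table + truth) to a directory
#' @param sim result of [simulate_dataset()].
#' @param dir output directory.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_counts_mtx(sim$counts, dir)
  write_tsv(sim$cells, file.path(dir, "cells.tsv"))
  write_tsv(sim$truth$genes, file.path(dir, "gene_truth.tsv"))
  write_tsv(sim$truth$cells, file.path(dir, "cell_truth.tsv"))
  write_sim_config(sim$truth$config, file.path(dir, "sim_config.tsv"))
  invisible(dir)
}
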