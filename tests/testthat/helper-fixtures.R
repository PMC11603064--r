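## Shared fixtures, built lazily and cached for the session so expensive
## simulations run once across test files.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (!exists(name, envir = .fixture_env)) assign(name, fn(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

## scaled-down world for plumbing tests (the acceptance suite uses the full
## 2000 x 4500 stated world)
small_config <- function(seed = 1, ...) {
  args <- list(n_genes = 300L, n_cells_per_sample = 80L,
               n_timing_shifted = 30L, n_tfs = 3L, targets_per_tf = 10L,
               seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

small_sim <- function() fixture("small_sim", function() simulate_dataset(small_config(seed = 42)))
small_null <- function() fixture("small_null", function() simulate_null_dataset(small_config(seed = 43)))

## a tiny deterministic count matrix with labels
toy_counts <- function(mat, genes = NULL, cells = NULL) {
  genes <- genes %||% sprintf("g%02d", seq_len(ncol(mat)))
  cells <- cells %||% sprintf("c%02d", seq_len(nrow(mat)))
  m <- methods::as(Matrix::Matrix(mat, sparse = TRUE), "CsparseMatrix")
  dimnames(m) <- list(cells, genes)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
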