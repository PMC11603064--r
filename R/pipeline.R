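#' Per-cluster dose differential expression
#'
#' Runs the ordinal-dose LRT (and optionally the pairwise Wald test) within
#' each cluster's pseudobulk family, calls DEGs, and classifies significant
#' genes as repressed / activated. Clusters whose pseudobulk cannot support
#' the design (fewer than 2 samples at some dose, or no all-nonzero gene)
#' are skipped with a warning.
#'
#' @param counts cells x genes count matrix.
#' @param cells cell table with `cluster`, `sample`, `dose`.
#' @param lfc_min,fdr DEG thresholds (defaults 0.2, 0.05).
#' @param wald_doses optional length-2 dose pair to add pairwise Wald
#'   columns; `NULL` to skip.
#' @return data.frame with one row per (cluster, gene): LRT statistics,
#'   `q`, `called`, `class`, and Wald columns if requested.
#' @export
run_dose_de <- function(counts, cells, lfc_min = 0.2, fdr = 0.05,
                        wald_doses = NULL) {
  out <- list()
  for (cl in sort(unique(cells$cluster))) {
    sel <- cells$cluster == cl
    pb <- tryCatch(aggregate_pseudobulk(counts[sel, , drop = FALSE],
                                        cells[sel, , drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(pb)) next
    per_dose <- table(pb$coldata$dose)
    if (length(per_dose) < 2 || any(per_dose < 2)) {
      warnf("cluster '%s' skipped: insufficient samples per dose", cl)
      next
    }
    res <- tryCatch({
      r <- call_degs(dose_lrt(pb), lfc_min = lfc_min, fdr = fdr)
      if (all(c("0", "1", "2") %in% names(per_dose)))
        r <- classify_dose_response(r, dose_means(pb), fdr = fdr)
      else r$class <- NA_character_
      r
    }, error = function(e) { warnf("cluster '%s': %s", cl, conditionMessage(e)); NULL })
    if (is.null(res)) next
    if (!is.null(wald_doses)) {
      w <- call_degs(wald_pairwise(pb, wald_doses), lfc_min = lfc_min, fdr = fdr)
      res$wald_log2fc <- w$log2fc; res$wald_p <- w$p; res$wald_q <- w$q
      res$wald_called <- w$called
    }
    res <- cbind(cluster = cl, res)
    out[[cl]] <- res
  }
  if (!length(out)) stopf("no cluster supported the dose design")
  do.call(rbind, c(out, make.row.names = FALSE))
}

validate_run_config <- function(config) {
  for (nm in c("burden", "timing", "regulon")) {
    stage <- config[[nm]]
    if (!is.null(stage) && !isFALSE(stage$enabled %||% TRUE) &&
        is.null(stage$seed))
      stopf("config validation: stage '%s' has no seed", nm)
  }
  invisible(config)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — qc, normalize, pseudobulk DE (+ burden),
#' composition, trajectory (pseudotime, dynamic genes, KS shifts, density
#' curves), KL timing, enrichment, regulons — writing one TSV per result
#' table under `outdir` plus `run_log.json` recording versions, seeds and
#' parameters. Any stage error aborts with the stage name; the seed
#' requirement for stochastic stages is validated before anything runs.
#'
#' @param counts cells x genes count matrix.
#' @param cells cell table (`cell`, `sample`, `dose`, `cluster`, `emb1`,
#'   `emb2`).
#' @param outdir output directory.
#' @param config nested list of stage parameters; see the vignette. Each of
#'   `burden`, `timing`, `regulon` needs an explicit `seed` (or
#'   `enabled = FALSE`). `enrich$gene_sets` / `regulon$regulons` are GMT
#'   paths or named lists; those stages are skipped when absent.
#' @return invisibly, the list of stage results.
#' @export
run_pipeline <- function(counts, cells, outdir, config = list()) {
  validate_run_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }

  qc_cfg <- config$qc %||% list()
  st <- stage("qc", {
    thr <- do.call(qc_thresholds, qc_cfg[setdiff(names(qc_cfg), "enabled")])
    apply_qc_filters(counts, cells, thr)
  })
  write_tsv(st$qc, file.path(outdir, "qc.tsv"))
  counts <- st$counts; cells <- st$cells
  results$qc <- st$qc

  norm <- stage("normalize",
                normalize_log(counts, config$normalize$scale %||% 10000))

  de_cfg <- config$de %||% list()
  results$de <- stage("de", run_dose_de(
    counts, cells, lfc_min = de_cfg$lfc_min %||% 0.2,
    fdr = de_cfg$fdr %||% 0.05, wald_doses = de_cfg$wald_doses %||% c(2, 0)))
  write_tsv(results$de, file.path(outdir, "de.tsv"))

  b_cfg <- config$burden %||% list(enabled = FALSE)
  if (!isFALSE(b_cfg$enabled %||% TRUE)) {
    results$burden <- stage("burden", deg_burden(
      counts, cells, doses = b_cfg$doses %||% c(2, 0),
      n_cells = b_cfg$n_cells %||% 700, reps = b_cfg$reps %||% 10,
      seed = b_cfg$seed))
    write_tsv(results$burden, file.path(outdir, "burden.tsv"))
  }

  results$composition <- stage("composition", {
    props <- proportions_table(cells)
    grp <- tapply(cells$dose, cells$sample, function(x) x[1])[rownames(props)]
    moderated_prop_test(props, grp)
  })
  write_tsv(results$composition, file.path(outdir, "composition.tsv"))

  tr_cfg <- config$trajectory %||% list()
  emb <- as.matrix(cells[, c("emb1", "emb2")])
  rownames(emb) <- cells$cell
  traj <- stage("trajectory", {
    root <- tr_cfg$root %||% cells$cell[which.min(cells$emb1)]
    assign_pseudotime(emb, root, k = tr_cfg$k %||% 15)
  })
  pt <- traj$pseudotime
  write_tsv(data.frame(cell = names(pt), pseudotime = pt),
            file.path(outdir, "pseudotime.tsv"))
  results$dynamic <- stage("trajectory", morans_i_test(norm, traj))
  write_tsv(results$dynamic, file.path(outdir, "dynamic_genes.tsv"))
  results$ks <- stage("trajectory", suppressWarnings(ks_shift_test(pt, cells)))
  write_tsv(results$ks, file.path(outdir, "ks_shift.tsv"))
  results$density <- stage("trajectory",
                           pseudotime_density_diff(pt, cells$dose,
                                                   bins = tr_cfg$bins %||% 10))
  write_tsv(results$density, file.path(outdir, "density_diff.tsv"))

  t_cfg <- config$timing %||% list(enabled = FALSE)
  if (!isFALSE(t_cfg$enabled %||% TRUE)) {
    results$timing <- stage("timing", {
      genes <- t_cfg$genes %||%
        utils::head(results$dynamic$gene[order(results$dynamic$q)], 100)
      kl <- kl_timing_test(norm, pt, cells$dose, genes = genes,
                           bins = t_cfg$bins %||% 20,
                           n_perm = t_cfg$n_perm %||% 1000, seed = t_cfg$seed)
      kl$table
    })
    write_tsv(results$timing, file.path(outdir, "timing.tsv"))
  }

  e_cfg <- config$enrich %||% list()
  if (!is.null(e_cfg$gene_sets)) {
    results$enrichment <- stage("enrich", {
      sets <- if (is.character(e_cfg$gene_sets)) read_gmt(e_cfg$gene_sets)
              else e_cfg$gene_sets
      universe <- colnames(counts)[Matrix::colSums(counts) > 0]
      query <- intersect(unique(results$de$gene[results$de$called]), universe)
      hypergeom_ora(query, universe, sets)
    })
    write_tsv(results$enrichment, file.path(outdir, "enrichment.tsv"))
  }

  r_cfg <- config$regulon %||% list()
  if (!is.null(r_cfg$regulons)) {
    results$regulons <- stage("regulon", {
      regs <- if (is.character(r_cfg$regulons)) read_gmt(r_cfg$regulons)
              else r_cfg$regulons
      act <- aucell_scores(counts, regs, top_frac = r_cfg$top_frac %||% 0.05,
                           seed = r_cfg$seed)
      rss <- regulon_specificity(act, cells$cluster)
      dr <- differential_regulons(act, cells)
      write_tsv(as.data.frame(cbind(regulon = rownames(rss), rss)),
                file.path(outdir, "rss.tsv"))
      dr
    })
    write_tsv(results$regulons, file.path(outdir, "regulons.tsv"))
  }

  log <- list(package = "doseDE",
              version = as.character(utils::packageVersion("doseDE")),
              r_version = R.version.string,
              date = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
              config = config)
  jsonlite::write_json(log, file.path(outdir, "run_log.json"),
                       auto_unbox = TRUE, null = "null", force = TRUE)
  invisible(results)
}
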