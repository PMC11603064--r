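#' Gene-wise NB GLM differential expression on a pseudobulk table
#'
#' Shared engine behind the pairwise Wald and ordinal-dose/interaction LRT
#' workflows. Fits [fit_nb_glm()] per gene with median-of-ratios size
#' factors and trend-shrunk dispersions (computed here unless supplied), then
#' either a Wald test on `contrast` or an LRT of `full` against `reduced`.
#' All-zero genes and non-converged fits carry `NA` statistics.
#'
#' @param pb_counts genes x columns integer matrix ([aggregate_pseudobulk()]).
#' @param coldata per-column covariates (must contain every variable named in
#'   the formulas).
#' @param full model formula for the full design, e.g. `~ dose`.
#' @param reduced reduced formula for an LRT; `NULL` for a Wald test.
#' @param contrast numeric contrast over the full-design coefficients (Wald
#'   path); `NULL` picks the last coefficient.
#' @param lfc_coef name of the coefficient reported as `log2fc` on the LRT
#'   path; defaults to the last full-design coefficient.
#' @param size_factors,dispersions optional precomputed values.
#' @return data.frame: gene, baseMean, log2fc, se, stat, df, p.
#' @export
nb_de <- function(pb_counts, coldata, full, reduced = NULL, contrast = NULL,
                  lfc_coef = NULL, size_factors = NULL, dispersions = NULL) {
  Y <- as.matrix(pb_counts)
  if (is.null(size_factors)) size_factors <- estimate_size_factors(Y)
  if (is.null(dispersions)) dispersions <- estimate_dispersions(Y, size_factors)
  X <- model.matrix(full, coldata)
  Xr <- if (!is.null(reduced)) model.matrix(reduced, coldata)
  if (!is.null(reduced) && ncol(Xr) >= ncol(X))
    stopf("reduced design must have fewer coefficients than the full design")
  if (is.null(contrast) && is.null(reduced)) {
    contrast <- c(rep(0, ncol(X) - 1), 1)
  }
  if (is.null(lfc_coef)) lfc_coef <- colnames(X)[ncol(X)]
  norm <- sweep(Y, 2, size_factors, "/")
  base_mean <- rowMeans(norm)

  n_genes <- nrow(Y)
  out <- data.frame(gene = rownames(Y) %||% as.character(seq_len(n_genes)),
                    baseMean = base_mean, log2fc = NA_real_, se = NA_real_,
                    stat = NA_real_, df = NA_integer_, p = NA_real_,
                    row.names = NULL, stringsAsFactors = FALSE)
  for (i in seq_len(n_genes)) {
    a <- dispersions[i]
    if (is.na(a) || all(Y[i, ] == 0)) next
    fit <- fit_nb_glm(Y[i, ], X, size_factors, a)
    if (is.null(reduced)) {
      wt <- wald_test(fit, contrast)
      out$log2fc[i] <- wt$estimate; out$se[i] <- wt$se
      out$stat[i] <- wt$z; out$df[i] <- 1L; out$p[i] <- wt$p
    } else {
      fit_r <- fit_nb_glm(Y[i, ], Xr, size_factors, a)
      lt <- lrt_test(fit, fit_r)
      j <- match(lfc_coef, fit$coef_names)
      out$log2fc[i] <- fit$beta[j]
      out$se[i] <- fit$se[j]
      out$stat[i] <- lt$lambda; out$df[i] <- lt$df; out$p[i] <- lt$p
    }
  }
  out
}

#' Pairwise Wald differential expression between two doses
#'
#' Subsets the pseudobulk columns to the two doses and tests the group
#' coefficient (log2 fold change of `doses[2]` over the reference
#' `doses[1]`).
#'
#' @param pb [aggregate_pseudobulk()] result (or a list with `counts`,
#'   `coldata`); `coldata` must have a `dose` column.
#' @param doses length-2 vector, reference first (default `c(2, 0)`:
#'   KO-vs-WT with WT as reference).
#' @return [nb_de()] table.
#' @export
wald_pairwise <- function(pb, doses = c(2, 0)) {
  keep <- pb$coldata$dose %in% doses
  cd <- pb$coldata[keep, , drop = FALSE]
  cd$group <- factor(cd$dose, levels = doses)
  nb_de(pb$counts[, keep, drop = FALSE], cd, ~group)
}

#' Ordinal gene-dose likelihood-ratio test
#'
#' The number of functional alleles (0 = KO, 1 = Het, 2 = WT) enters the
#' full model as a numeric covariate, so the test has 1 df and the reported
#' `log2fc` is the per-allele slope. Extra covariates (e.g. `~ sex`) can be
#' carried in both designs via `covariates`.
#'
#' @param pb [aggregate_pseudobulk()] result with `dose` in `coldata`.
#' @param covariates optional one-sided formula of additional covariates.
#' @return [nb_de()] table (LRT statistics, per-allele log2 slope).
#' @export
dose_lrt <- function(pb, covariates = NULL) {
  cd <- pb$coldata
  cd$dose_num <- as.numeric(cd$dose)
  if (is.null(covariates)) {
    full <- ~dose_num; reduced <- ~1
  } else {
    cv <- paste(all.vars(covariates), collapse = " + ")
    full <- stats::as.formula(paste("~", cv, "+ dose_num"))
    reduced <- stats::as.formula(paste("~", cv))
  }
  nb_de(pb$counts, cd, full, reduced = reduced, lfc_coef = "dose_num")
}

#' Interaction LRT (covariate x genotype-dose)
#'
#' Tests whether the dose response differs across the levels of `covariate`
#' (e.g. sex or age): full `~ covariate + dose + covariate:dose` against the
#' additive reduced model.
#'
#' @param pb [aggregate_pseudobulk()] result.
#' @param covariate name of a column of `pb$coldata`.
#' @return [nb_de()] table.
#' @export
interaction_lrt <- function(pb, covariate) {
  cd <- pb$coldata
  if (!covariate %in% names(cd)) stopf("coldata has no column '%s'", covariate)
  cd$dose_num <- as.numeric(cd$dose)
  cd$.cv <- factor(cd[[covariate]])
  nb_de(pb$counts, cd, ~.cv + dose_num + .cv:dose_num,
        reduced = ~.cv + dose_num)
}

#' Call differentially expressed genes
#'
#' BH-adjusts the p-values of one result family and flags genes with
#' `q < fdr` and `|log2fc| >= lfc_min` as called, recording direction.
#'
#' @param res an [nb_de()] table (one family, e.g. one cluster x contrast).
#' @param lfc_min minimum absolute log2 fold change (default 0.2).
#' @param fdr FDR threshold (default 0.05).
#' @return `res` with `q`, `called`, `direction` columns.
#' @export
call_degs <- function(res, lfc_min = 0.2, fdr = 0.05) {
  res$q <- bh_adjust(res$p)
  res$called <- !is.na(res$q) & res$q < fdr &
    !is.na(res$log2fc) & abs(res$log2fc) >= lfc_min
  res$direction <- ifelse(res$called, ifelse(res$log2fc > 0, "up", "down"), "ns")
  res
}

#' Normalized mean expression per dose
#'
#' @param pb [aggregate_pseudobulk()] result with `dose` in `coldata`.
#' @param size_factors optional precomputed size factors.
#' @return genes x doses matrix of mean normalized pseudobulk expression,
#'   columns named by dose.
#' @export
dose_means <- function(pb, size_factors = NULL) {
  if (is.null(size_factors)) size_factors <- estimate_size_factors(pb$counts)
  norm <- sweep(as.matrix(pb$counts), 2, size_factors, "/")
  doses <- sort(unique(pb$coldata$dose))
  out <- sapply(doses, function(d)
    rowMeans(norm[, pb$coldata$dose == d, drop = FALSE]))
  colnames(out) <- as.character(doses)
  out
}

#' Classify dose-LRT-significant genes as repressed or activated
#'
#' Among genes with dose-LRT `q < fdr`, a gene is `repressed` if its mean
#' normalized expression peaks at dose 0 (highest in KO — de-repressed on
#' loss) and `activated` if it peaks at dose 2 (highest in WT). Genes peaking
#' at dose 1 are flagged `non-monotone` and belong to neither class; all
#' other genes are `ns`.
#'
#' @param res a [dose_lrt()] table passed through [call_degs()] (has `q`).
#' @param means a [dose_means()] matrix with columns `"0"`, `"1"`, `"2"`.
#' @param fdr significance threshold on the LRT q-value (default 0.05).
#' @return `res` with a `class` column.
#' @export
classify_dose_response <- function(res, means, fdr = 0.05) {
  need <- c("0", "1", "2")
  if (!all(need %in% colnames(means)))
    stopf("dose means must cover doses 0, 1 and 2 (missing: %s)",
          paste(setdiff(need, colnames(means)), collapse = ", "))
  peak <- need[max.col(means[, need, drop = FALSE], ties.method = "first")]
  sig <- !is.na(res$q) & res$q < fdr
  res$class <- "ns"
  res$class[sig & peak == "0"] <- "repressed"
  res$class[sig & peak == "2"] <- "activated"
  res$class[sig & peak == "1"] <- "non-monotone"
  res
}
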