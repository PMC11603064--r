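#' Per-sample cell-type proportion table
#'
#' @param cells cell table with `sample` and a label column.
#' @param by name of the label column (default `"cluster"`; pass `"phase"`
#'   to analyse cell-cycle phase proportions with the same machinery).
#' @return samples x labels matrix of proportions (rows sum to 1), with
#'   per-sample totals in `attr(, "totals")`. Empty samples are dropped with
#'   a warning.
#' @export
proportions_table <- function(cells, by = "cluster") {
  if (!all(c("sample", by) %in% names(cells)))
    stopf("cell table needs 'sample' and '%s' columns", by)
  tab <- table(cells$sample, cells[[by]])
  totals <- rowSums(tab)
  if (any(totals == 0)) {
    warnf("dropping empty sample(s): %s",
          paste(rownames(tab)[totals == 0], collapse = ", "))
    tab <- tab[totals > 0, , drop = FALSE]
    totals <- totals[totals > 0]
  }
  props <- sweep(unclass(tab), 1, totals, "/")
  attr(props, "totals") <- totals
  props
}

#' Moderated test of proportion differences across groups
#'
#' Proportions are variance-stabilised with the arcsin-square-root transform,
#' then each cluster gets a linear model across samples on the group factor.
#' Residual variances are shrunk across clusters by empirical Bayes
#' (scaled-inverse-chi-square prior, moments fit — `limma::squeezeVar`),
#' giving a moderated t for two groups and a moderated F for three or more,
#' with BH adjustment across clusters.
#'
#' @param props a [proportions_table()].
#' @param groups group label per sample (row of `props`), e.g. dose.
#' @param prior_df override for the prior degrees of freedom; `NULL`
#'   (default) estimates the prior by moments, `0` disables moderation so
#'   the statistic reduces to the ordinary t / F.
#' @return data.frame: cluster, statistic, df1 (F only), df_total, p, q,
#'   plus the shrunk variance.
#' @export
moderated_prop_test <- function(props, groups, prior_df = NULL) {
  groups <- factor(groups)
  if (length(groups) != nrow(props))
    stopf("groups length must match the number of samples")
  sizes <- table(groups)
  if (any(sizes < 2))
    stopf("group(s) with fewer than 2 samples: %s",
          paste(names(sizes)[sizes < 2], collapse = ", "))
  y <- asin(sqrt(props))
  k <- nlevels(groups)
  n <- nrow(props)
  df_res <- n - k

  X <- model.matrix(~groups)
  qrX <- qr(X)
  fit_stats <- apply(y, 2, function(v) {
    res <- qr.resid(qrX, v)
    rss1 <- sum(res^2)
    rss0 <- sum((v - mean(v))^2)
    coefs <- qr.coef(qrX, v)
    c(rss0 = rss0, rss1 = rss1,
      effect = if (k == 2) unname(coefs[2]) else NA_real_)
  })
  ## clusters with (numerically) no variation across samples: stat 0, p 1
  flat <- fit_stats["rss0", ] <= 1e-20
  s2 <- fit_stats["rss1", ] / df_res
  sq <- if (!is.null(prior_df) && prior_df == 0)
    list(var.post = s2, df.prior = 0)
  else if (all(s2 == 0)) list(var.post = s2, df.prior = Inf)
  else limma::squeezeVar(s2, df = df_res)
  df_total <- df_res + sq$df.prior
  out <- data.frame(cluster = colnames(props), stringsAsFactors = FALSE)
  if (k == 2) {
    g2 <- levels(groups)[2]
    inv_n <- 1 / sizes[[1]] + 1 / sizes[[g2]]
    se <- sqrt(sq$var.post * inv_n)
    num <- fit_stats["effect", ]
    tstat <- ifelse(flat | num == 0, 0, num / se)
    out$statistic <- tstat
    out$df_total <- df_total
    out$p <- ifelse(tstat == 0, 1,
                    2 * pt(-abs(tstat), df = pmin(df_total, 1e6)))
  } else {
    num <- (fit_stats["rss0", ] - fit_stats["rss1", ]) / (k - 1)
    fstat <- ifelse(flat | num <= 0, 0, num / sq$var.post)
    out$statistic <- fstat
    out$df1 <- k - 1
    out$df_total <- df_total
    out$p <- ifelse(fstat == 0, 1,
                    pf(fstat, k - 1, pmin(df_total, 1e6), lower.tail = FALSE))
  }
  out$var_post <- sq$var.post
  out$q <- bh_adjust(out$p)
  out
}
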