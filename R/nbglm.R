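#' Fit a negative-binomial GLM for one gene
#'
#' IRLS maximisation of the NB log-likelihood with log link, fixed dispersion
#' `alpha` (variance `mu + alpha mu^2`) and offset `log(size_factors)`.
#' The fit is performed on the natural-log scale and reported on the log2
#' scale (coefficients and covariance divided by `ln 2` and `ln(2)^2`), so
#' fold-change thresholds in log2 units apply directly. Convergence is
#' declared when the largest coefficient update falls below `tol` (natural
#' log scale); non-converged fits are flagged, and downstream tests report
#' missing statistics for them.
#'
#' @param y integer counts, one per pseudobulk column.
#' @param X design matrix (full column rank), rows matching `y`.
#' @param size_factors positive size factors, one per observation.
#' @param alpha NB dispersion (scalar, >= 0; 0 is treated as 1e-8 ~ Poisson).
#' @param tol,max_iter IRLS stopping rule (defaults 1e-8, 100).
#' @return list: `beta` (log2), `se` (log2), `cov` (log2 scale), `loglik`,
#'   `df` (number of coefficients), `converged`, `mu` (fitted means).
#' @export
fit_nb_glm <- function(y, X, size_factors = rep(1, length(y)), alpha,
                       tol = 1e-8, max_iter = 100) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stopf("design rows must match observations")
  if (qr(X)$rank < ncol(X)) stopf("design matrix is not full column rank")
  alpha <- max(alpha, 1e-8)
  off <- log(size_factors)
  ## init from a linear fit to log counts
  b <- qr.coef(qr(X), log(y + 0.5) - off)
  b[is.na(b)] <- 0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- pmin(drop(X %*% b) + off, 30)
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    z <- (eta - off) + (y - mu) / mu
    XtW <- t(X * w)
    b_new <- tryCatch(solve(XtW %*% X, XtW %*% z)[, 1],
                      error = function(e) rep(NA_real_, ncol(X)))
    if (anyNA(b_new)) break
    delta <- max(abs(b_new - b))
    b <- b_new
    if (delta < tol) { converged <- TRUE; break }
  }
  eta <- pmin(drop(X %*% b) + off, 30)
  mu <- exp(eta)
  w <- mu / (1 + alpha * mu)
  info <- t(X * w) %*% X
  cov_ln <- tryCatch(solve(info), error = function(e)
    matrix(NA_real_, ncol(X), ncol(X)))
  ll <- sum(dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
  ln2 <- log(2)
  list(beta = b / ln2, se = sqrt(diag(cov_ln)) / ln2, cov = cov_ln / ln2^2,
       loglik = ll, df = ncol(X), converged = converged, mu = mu,
       coef_names = colnames(X))
}

#' Wald test of a linear contrast
#'
#' `z = c'beta / sqrt(c' Sigma c)` with a two-sided normal p-value. The
#' contrast applies to the log2-scale coefficients of [fit_nb_glm()].
#'
#' @param fit a [fit_nb_glm()] result.
#' @param contrast numeric vector, one entry per coefficient.
#' @return list: `estimate` (log2), `se`, `z`, `p` (all `NA` if the
#'   covariance is singular or the fit did not converge).
#' @export
wald_test <- function(fit, contrast) {
  if (length(contrast) != length(fit$beta))
    stopf("contrast length (%d) must equal the number of coefficients (%d)",
          length(contrast), length(fit$beta))
  est <- sum(contrast * fit$beta)
  v <- drop(t(contrast) %*% fit$cov %*% contrast)
  if (!fit$converged || !is.finite(v) || v < 0)
    return(list(estimate = est, se = NA_real_, z = NA_real_, p = NA_real_))
  se <- sqrt(v)
  z <- if (se == 0) 0 else est / se
  list(estimate = est, se = se, z = z, p = 2 * pnorm(-abs(z)))
}

#' Likelihood-ratio test between nested NB fits
#'
#' `lambda = 2 (ll_full - ll_reduced)` against a chi-square with df equal to
#' the difference in coefficient count. Both fits must use the same
#' dispersion; nesting is checked by df only (the caller owns the designs).
#'
#' @param fit_full,fit_reduced [fit_nb_glm()] results, reduced nested in full.
#' @return list: `lambda`, `df`, `p`.
#' @export
lrt_test <- function(fit_full, fit_reduced) {
  df <- fit_full$df - fit_reduced$df
  if (df < 0) stopf("designs are not nested (reduced has more coefficients)")
  lambda <- max(2 * (fit_full$loglik - fit_reduced$loglik), 0)
  if (!fit_full$converged || !fit_reduced$converged)
    return(list(lambda = NA_real_, df = df, p = NA_real_))
  ## identical designs: degenerate chi-square at 0
  p <- if (df == 0) as.numeric(lambda < 1e-8)
       else pchisq(lambda, df, lower.tail = FALSE)
  list(lambda = lambda, df = df, p = p)
}
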