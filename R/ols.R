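#' @keywords internal
"_PACKAGE"

# Shared least-squares machinery. Every model in the package is an OLS fit of a
# continuous outcome on a small set of standardized exposure columns, so a
# single fast fitter (QR with pivoting, aliased columns reported rather than
# silently dropped) backs screening, stepwise selection and the probes.

#' Ordinary least squares with full inference
#'
#' Fits \code{y ~ 1 + X} by pivoted QR and returns coefficients, standard
#' errors, t statistics, two-sided p-values from the t reference distribution,
#' R-squared and the residual degrees of freedom. Aliased (collinear) columns
#' are reported by name with \code{NA} coefficients.
#'
#' @param X numeric matrix of predictors (may be \code{NULL} for the
#'   intercept-only model); column names are used as term labels.
#' @param y numeric response vector.
#' @return list with elements \code{coef}, \code{se}, \code{t}, \code{p},
#'   \code{df}, \code{rss}, \code{tss}, \code{r_squared}, \code{fitted},
#'   \code{residuals}, \code{aliased}, \code{n}.
#' @keywords internal
ols <- function(X, y) {
  n <- length(y)
  if (is.null(X)) {
    Xd <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    X <- as.matrix(X)
    Xd <- cbind("(Intercept)" = rep(1, n), X)
  }
  fit <- stats::lm.fit(Xd, y)
  rank <- fit$rank
  piv <- fit$qr$pivot
  cf <- fit$coefficients
  aliased <- names(cf)[is.na(cf)]
  rss <- sum(fit$residuals^2)
  df <- n - rank
  tss <- sum((y - mean(y))^2)
  se <- rep(NA_real_, length(cf))
  names(se) <- names(cf)
  if (df > 0) {
    sigma2 <- rss / df
    R <- fit$qr$qr[seq_len(rank), seq_len(rank), drop = FALSE]
    R[lower.tri(R)] <- 0
    xtxinv <- chol2inv(R)
    se[piv[seq_len(rank)]] <- sqrt(pmax(diag(xtxinv), 0) * sigma2)
  }
  tval <- cf / se
  pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  list(coef = cf, se = se, t = tval, p = pval, df = df, rss = rss, tss = tss,
       r_squared = if (tss > 0) max(1 - rss / tss, 0) else 0,
       fitted = fit$fitted.values, residuals = fit$residuals,
       aliased = aliased, n = n)
}

# residuals of each column of M on the column space of Xd (with intercept),
# used to compute partial tests for a whole candidate block at once
residualize <- function(M, qr_obj) {
  M - qr.fitted(qr_obj, M)
}
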