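# Missing-value imputation by chained equations over the stage-1-selected
# variables, and Rubin's rules for pooling final-model coefficients across
# completed datasets.
#
# The engine is a purpose-built implementation of the standard algorithm:
# every variable with missingness gets a conditional model on the other
# variables (Bayesian linear "norm" draws for continuous variables, logistic
# regression with parameter draws for binary ones, type-1 predictive-mean
# matching for ordinal ones), cycled a fixed number of times per imputation.
# The analysis outcome participates as a predictor in every conditional
# model, which is required for the completed data to be congenial with the
# analysis model, but outcome cells themselves are never returned imputed.

#' Chained-equations imputation
#'
#' Produces \code{M} completed copies of the exposome. Observed entries are
#' never altered; convention-filled partner cells count as observed. The
#' imputation sample is all subjects supplied (typically larger than the
#' outcome-observed analysis sample): subjects without an outcome still
#' inform the conditional models through their exposures.
#'
#' @param em an \code{\link{exposome_matrix}} restricted to the stage-1
#'   selected variables (plus partner status, carried by the object).
#' @param outcome numeric outcome vector; used as a predictor where observed
#'   (and chained over where missing), never returned imputed.
#' @param M number of imputations (default 5).
#' @param n_iter chained-equation cycles per imputation (default 10).
#' @param seed RNG seed.
#' @param max_predictors cap on predictors per conditional model; when
#'   finite, the predictors with the largest absolute correlation with the
#'   target (plus partner status and the outcome) are used, in the manner of
#'   quickpred-style predictor selection at exposome scale. Default:
#'   unlimited.
#' @param donors donor-pool size for predictive-mean matching (default 5).
#' @return object of class \code{imputation_set}: list with
#'   \code{imputations} (completed \code{exposome_matrix} objects),
#'   \code{methods}, \code{M}, \code{n_iter}, \code{seed}, \code{trace}
#'   (per-imputation, per-iteration chain means of imputed cells) and
#'   \code{provenance} (predictor sets).
#' @export
mice_impute <- function(em, outcome, M = 5, n_iter = 10, seed = NULL,
                        max_predictors = Inf, donors = 5L) {
  if (!is.null(seed)) set.seed(seed)
  X <- em$data
  n <- nrow(X); m <- ncol(X)
  vt <- em$codebook$var_type
  dat <- cbind(X, .outcome. = outcome, .partner_status. = em$partner_status)
  types <- c(stats::setNames(vt, colnames(X)),
             .outcome. = "continuous", .partner_status. = "complete")
  mis <- is.na(dat)
  all_missing <- colnames(dat)[colSums(mis) == n]
  if (length(all_missing))
    stop("variable(s) with 100% missingness cannot be imputed: ",
         paste(all_missing, collapse = ", "))
  targets <- colnames(dat)[colSums(mis) > 0 &
                             colnames(dat) != ".partner_status."]
  methods <- vapply(targets, function(v) switch(types[[v]],
    continuous = "norm", binary = "logreg", ordinal = "pmm",
    complete = "none"), character(1))

  if (!length(targets)) {
    imps <- replicate(M, em, simplify = FALSE)
    return(structure(list(imputations = imps, methods = methods, M = M,
                          n_iter = n_iter, seed = seed, trace = list(),
                          provenance = list()),
                     class = "imputation_set"))
  }

  # initial fill: sampled observed values
  init_fill <- function(d) {
    for (v in targets) {
      o <- d[!mis[, v], v]
      d[mis[, v], v] <- sample(o, sum(mis[, v]), replace = TRUE)
    }
    d
  }

  # fixed predictor sets, chosen once on an initially filled copy
  d0 <- init_fill(dat)
  pred_of <- lapply(targets, function(v) {
    others <- setdiff(colnames(dat), v)
    others <- others[apply(d0[, others, drop = FALSE], 2,
                           function(x) stats::sd(x) > 0)]
    if (is.finite(max_predictors) && length(others) > max_predictors) {
      r <- abs(suppressWarnings(stats::cor(d0[, v], d0[, others])))[1, ]
      keep <- names(sort(r, decreasing = TRUE))[seq_len(max_predictors)]
      others <- union(keep,
                      intersect(c(".outcome.", ".partner_status."), others))
    }
    others
  })
  names(pred_of) <- targets

  imps <- vector("list", M)
  trace <- vector("list", M)
  for (imp in seq_len(M)) {
    d <- init_fill(dat)
    tr <- matrix(NA_real_, n_iter, length(targets),
                 dimnames = list(NULL, targets))
    for (it in seq_len(n_iter)) {
      for (v in targets) {
        w <- mis[, v]
        Xp <- d[, pred_of[[v]], drop = FALSE]
        d[w, v] <- draw_conditional(d[, v], Xp, w, methods[[v]], donors)
        tr[it, v] <- mean(d[w, v])
      }
    }
    comp <- em
    comp$data <- d[, colnames(X), drop = FALSE]
    imps[[imp]] <- comp
    trace[[imp]] <- tr
  }
  structure(list(imputations = imps, methods = methods, M = M,
                 n_iter = n_iter, seed = seed, trace = trace,
                 provenance = pred_of),
            class = "imputation_set")
}

#' @export
print.imputation_set <- function(x, ...) {
  cat("imputation_set:", x$M, "imputation(s),", x$n_iter, "cycles,",
      length(x$methods), "imputed variable(s)\n")
  if (length(x$methods))
    print(table(unlist(x$methods)))
  invisible(x)
}

#' Extract one completed dataset
#'
#' @param imp an \code{imputation_set}.
#' @param i which imputation (default 1, the dataset designated for model
#'   selection).
#' @return a completed \code{\link{exposome_matrix}}.
#' @export
complete_data <- function(imp, i = 1L) {
  stopifnot(inherits(imp, "imputation_set"))
  imp$imputations[[i]]
}

# one Gibbs update for a single variable; returns draws for the missing rows
draw_conditional <- function(yv, Xp, w, method, donors) {
  Xo <- Xp[!w, , drop = FALSE]; yo <- yv[!w]
  Xm <- Xp[w, , drop = FALSE]
  if (method == "logreg") {
    lev <- sort(unique(yo))
    if (length(lev) != 2) method <- "pmm"  # degenerate under current fill
  }
  if (method %in% c("norm", "pmm")) {
    bd <- bayes_lm_draw(Xo, yo)
    eta_m <- drop(cbind(1, Xm) %*% bd$beta_draw)
    if (method == "norm") return(eta_m + stats::rnorm(sum(w), 0, bd$sigma))
    # type-1 PMM: drawn parameters for the missing, MLE for the observed
    eta_o <- drop(cbind(1, Xo) %*% bd$beta_hat)
    idx <- pmm_match(eta_o, eta_m, donors)
    return(yo[idx])
  }
  if (method == "logreg") {
    yb <- as.numeric(yv == max(yv[!w]))
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(cbind(1, Xo), yb[!w],
                                      family = stats::binomial())),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged || fit$rank < ncol(Xo) + 1) {
      # separation or collinearity: fall back to matching on a linear fit
      bd <- bayes_lm_draw(Xo, yv[!w])
      eta_m <- drop(cbind(1, Xm) %*% bd$beta_draw)
      eta_o <- drop(cbind(1, Xo) %*% bd$beta_hat)
      return(yv[!w][pmm_match(eta_o, eta_m, donors)])
    }
    Q <- qr.R(fit$qr)
    cov <- chol2inv(Q)
    beta <- fit$coefficients +
      drop(t(chol(cov)) %*% stats::rnorm(length(fit$coefficients)))
    pm <- stats::plogis(drop(cbind(1, Xm) %*% beta))
    lev <- sort(unique(yv[!w]))
    return(lev[1 + stats::rbinom(sum(w), 1, pm)])
  }
  stop("unknown conditional method: ", method)
}

# proper Bayesian draw for the normal linear model (Jeffreys prior):
# sigma^2 from the scaled inverse chi-square, beta from its normal posterior
bayes_lm_draw <- function(Xo, yo) {
  Xd <- cbind(1, Xo)
  qrx <- qr(Xd)
  r <- qrx$rank
  if (r < ncol(Xd)) {          # drop aliased columns
    keep <- qrx$pivot[seq_len(r)]
    Xd <- Xd[, keep, drop = FALSE]
    qrx <- qr(Xd)
    full_keep <- keep
  } else full_keep <- seq_len(ncol(Xd))
  bhat <- qr.coef(qrx, yo)
  res <- yo - drop(Xd %*% bhat)
  df <- max(length(yo) - r, 1)
  sigma2 <- sum(res^2) / stats::rchisq(1, df)
  R <- qr.R(qrx)
  Rinv <- backsolve(R, diag(r))
  beta_draw <- bhat + sqrt(sigma2) * drop(Rinv %*% stats::rnorm(r))
  # re-expand to full coefficient vectors (aliased columns get 0)
  full_b <- numeric(ncol(Xo) + 1); full_b[full_keep] <- bhat
  full_d <- numeric(ncol(Xo) + 1); full_d[full_keep] <- beta_draw
  list(beta_hat = full_b, beta_draw = full_d, sigma = sqrt(sigma2))
}

# for each element of eta_m, sample one of the `donors` nearest eta_o values
pmm_match <- function(eta_o, eta_m, donors) {
  no <- length(eta_o)
  d <- min(donors, no)
  ord <- order(eta_o)
  eo <- eta_o[ord]
  pos <- findInterval(eta_m, eo)
  vapply(seq_along(eta_m), function(i) {
    lo <- max(1, pos[i] - d); hi <- min(no, pos[i] + d)
    window <- ord[lo:hi]
    dist <- abs(eta_o[window] - eta_m[i])
    window[order(dist)[sample.int(min(d, length(window)), 1)]]
  }, integer(1))
}

#' Pool per-imputation model fits by Rubin's rules
#'
#' Pooled coefficient = mean across imputations; pooled variance = within +
#' (1 + 1/M) between; degrees of freedom by the Barnard-Rubin small-sample
#' adjustment. With M = 1 the single fit is returned unchanged.
#'
#' @param fits list of \code{model_fit} objects over the same variable set
#'   (one per completed dataset).
#' @return a pooled \code{model_fit} (method tag \code{"pooled"}), with
#'   per-term between/within variance recorded in \code{$pooling}.
#' @export
pool_rubin <- function(fits) {
  stopifnot(length(fits) >= 1)
  M <- length(fits)
  terms <- lapply(fits, function(f) f$table$term)
  if (!all(vapply(terms, identical, logical(1), y = terms[[1]])))
    stop("fits have mismatched variable sets; cannot pool")
  if (M == 1) return(fits[[1]])
  cf <- sapply(fits, function(f) f$table$B)
  se <- sapply(fits, function(f) f$table$se)
  qbar <- rowMeans(cf)
  W <- rowMeans(se^2)
  B <- apply(cf, 1, stats::var)
  Tv <- W + (1 + 1 / M) * B
  lam <- pmin(pmax((1 + 1 / M) * B / Tv, 1e-12), 1 - 1e-12)
  df_com <- fits[[1]]$df
  nu_old <- (M - 1) / lam^2
  nu_obs <- (df_com + 1) / (df_com + 3) * df_com * (1 - lam)
  nu <- nu_old * nu_obs / (nu_old + nu_obs)
  tstat <- qbar / sqrt(Tv)
  p <- 2 * stats::pt(abs(tstat), nu, lower.tail = FALSE)
  hw <- stats::qt(0.975, nu) * sqrt(Tv)
  tab <- fits[[1]]$table
  tab$B <- qbar; tab$se <- sqrt(Tv)
  tab$ci_lo <- qbar - hw; tab$ci_hi <- qbar + hw
  tab$t <- tstat; tab$p <- p
  tab$partial_r <- NA_real_
  out <- fits[[1]]
  out$table <- tab
  out$method <- "pooled"
  out$r_squared <- mean(vapply(fits, function(f) f$r_squared, numeric(1)))
  out$df <- stats::median(nu)
  out$pooling <- data.frame(term = tab$term, within = W, between = B,
                            total = Tv, df = nu)
  out
}
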