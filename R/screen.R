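# Stage-1 univariable screening: one OLS fit of the outcome per exposure
# (co-adjusted for partner status when the exposure is partner-reported),
# a false-discovery-rate pass criterion across the whole family of tests,
# Q-Q plot data, and a prior-hypothesis exemption route.

#' Univariable exposome scan
#'
#' Regresses the outcome on each exposure in turn (intercept + variable,
#' plus the partner-status indicator when the variable is partner-reported),
#' on the subjects with an observed outcome and an observed value for that
#' variable. Returns the slope in outcome units per exposure SD (if the
#' matrix is standardized), its standard error, the two-sided p-value from
#' the t reference distribution, and the variance explained; variables are
#' ranked by descending variance explained. For partner-reported variables
#' the variance explained is the increment over the partner-status-only
#' model on the same subjects.
#'
#' Mother-reported variables are fitted in closed form for all columns at
#' once, so scans of thousands of variables are cheap.
#'
#' @param em a standardized \code{\link{exposome_matrix}}.
#' @param outcome numeric outcome vector (\code{NA} = not in analysis).
#' @return a \code{data.frame} of class \code{screen_result} with columns
#'   \code{name}, \code{domain}, \code{B}, \code{se}, \code{p}, \code{r2},
#'   \code{n}, \code{rank}.
#' @export
univariable_scan <- function(em, outcome) {
  rows <- !is.na(outcome)
  X <- em$data[rows, , drop = FALSE]
  y <- outcome[rows]
  ps <- em$partner_status[rows]
  m <- ncol(X)
  is_partner <- em$codebook$reporter == "partner"

  if (anyNA(X)) {
    obs <- !is.na(X)
    X0 <- X; X0[!obs] <- 0
    nj <- colSums(obs)
    sx <- colSums(X0)
    sxx <- colSums(X0^2)
    sxy <- colSums(X0 * y)
    sy <- colSums(obs * y)
    syy <- colSums(obs * y^2)
  } else {
    # complete-data fast path: one BLAS pass instead of masked sums
    obs <- matrix(TRUE, nrow(X), ncol(X))
    nj <- rep(length(y), m)
    sx <- colSums(X)
    sxx <- colSums(X^2)
    sxy <- drop(crossprod(X, y))
    sy <- rep(sum(y), m)
    syy <- rep(sum(y^2), m)
  }
  sxx_c <- sxx - sx^2 / nj
  syy_c <- syy - sy^2 / nj
  if (any(sxx_c <= 1e-12 * pmax(sxx, 1)))
    stop("degenerate column(s) in scan (constant among analysis subjects): ",
         paste(utils::head(colnames(X)[sxx_c <= 1e-12 * pmax(sxx, 1)], 5),
               collapse = ", "), "; run drop_degenerate() first")
  B <- (sxy - sx * sy / nj) / sxx_c
  rss <- syy_c - B^2 * sxx_c
  df <- nj - 2
  se <- sqrt(pmax(rss, 0) / df / sxx_c)
  r2 <- 1 - rss / syy_c

  # partner-reported variables: co-adjust for partner status
  for (j in which(is_partner)) {
    ok <- obs[, j]
    f1 <- ols(cbind(x = X[ok, j], partner_status = ps[ok]), y[ok])
    f0 <- ols(cbind(partner_status = ps[ok]), y[ok])
    B[j] <- f1$coef[["x"]]
    se[j] <- f1$se[["x"]]
    df[j] <- f1$df
    r2[j] <- (f0$rss - f1$rss) / f1$tss  # semi-partial increment
  }
  p <- 2 * stats::pt(abs(B / se), df, lower.tail = FALSE)

  out <- data.frame(name = colnames(X), domain = em$codebook$domain,
                    B = B, se = se, p = p, r2 = r2, n = nj,
                    stringsAsFactors = FALSE)
  out$rank <- rank(-out$r2, ties.method = "first")
  rownames(out) <- NULL
  class(out) <- c("screen_result", "data.frame")
  out
}

#' False-discovery-rate pass criterion
#'
#' Benjamini-Hochberg step-up at family-wide rate \code{q}: with the
#' p-values sorted ascending, the criterion is the largest index i with
#' p(i) <= i q / m. Geometrically this is a variable criterion running from
#' the nominal level for the largest p-value down to the Bonferroni critical
#' value q/m for the smallest, and the operative cutoff is where that line
#' intersects the observed p-values. Two equivalent statements of the cutoff
#' are returned: \code{threshold} = p(i*) (the intersection point; pass flags
#' are p <= threshold) and \code{critical_value} = i* q / m (the nominal
#' p-value criterion quoted for downstream model selection). Both flag the
#' identical discovery set. If no index qualifies nothing passes.
#'
#' @param pvalues numeric p-values in [0,1].
#' @param q family-wide rate (default 0.001).
#' @return object of class \code{fdr_decision}: list with \code{m}, \code{q},
#'   \code{threshold}, \code{critical_value}, \code{bonferroni_floor},
#'   \code{n_pass}, \code{pass} (logical, in input order).
#' @export
fdr_threshold <- function(pvalues, q = 0.001) {
  if (length(pvalues) == 0) stop("empty p-value vector")
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0,1]")
  if (q <= 0 || q >= 1) stop("q must be in (0,1)")
  m <- length(pvalues)
  ord <- sort(pvalues)
  ok <- which(ord <= seq_len(m) * q / m)
  if (length(ok)) {
    istar <- max(ok)
    threshold <- ord[istar]
    critical <- istar * q / m
    pass <- pvalues <= threshold
  } else {
    threshold <- 0
    critical <- 0
    pass <- rep(FALSE, m)
  }
  structure(list(m = m, q = q, threshold = threshold,
                 critical_value = critical, bonferroni_floor = q / m,
                 n_pass = sum(pass), pass = pass),
            class = "fdr_decision")
}

#' @export
print.fdr_decision <- function(x, ...) {
  cat(sprintf(
    "FDR step-up: m = %d tests, family-wide rate q = %g\n", x$m, x$q))
  cat(sprintf("  criterion p <= %.6g (nominal critical value %.6g,",
              x$threshold, x$critical_value))
  cat(sprintf(" Bonferroni floor %.3g)\n  discoveries: %d\n",
              x$bonferroni_floor, x$n_pass))
  invisible(x)
}

#' Q-Q plot coordinates for a p-value family
#'
#' Observed p-values sorted ascending against uniform expected quantiles
#' i/(m+1), both on the -log10 scale, suitable for the classic scan Q-Q plot
#' with the FDR criterion line overlaid. Zero p-values are floored at the
#' smallest representable double.
#'
#' @param pvalues numeric p-values.
#' @return data.frame with \code{expected} and \code{observed} columns.
#' @export
qq_plot_data <- function(pvalues) {
  if (length(pvalues) == 0) stop("empty p-value vector")
  m <- length(pvalues)
  obs <- sort(pmax(pvalues, .Machine$double.xmin))
  data.frame(expected = -log10(seq_len(m) / (m + 1)),
             observed = -log10(obs))
}

#' Combine scan results with an FDR decision and prior hypotheses
#'
#' Attaches pass flags to a scan. Variables named in \code{prior_list} are
#' exempt from the family-wide criterion: prior evidence from other studies
#' weakens the inclusion criterion for those particular variables to a
#' nominal level (default 0.05). The \code{route} column records whether a
#' variable passed via the FDR criterion, the prior exemption, or not at
#' all.
#'
#' @param results a \code{screen_result} from \code{\link{univariable_scan}}.
#' @param decision an \code{fdr_decision} for \code{results$p} (computed at
#'   \code{q} if omitted).
#' @param prior_list character vector of prior-hypothesis variable names.
#' @param nominal_alpha exemption level for prior variables (default 0.05).
#' @param q family-wide rate used when \code{decision} is omitted.
#' @return \code{results} with \code{passes_fdr} and \code{route} columns;
#'   the decision is attached as attribute \code{"fdr"}.
#' @export
apply_prior_hypotheses <- function(results, prior_list = character(0),
                                   decision = NULL, nominal_alpha = 0.05,
                                   q = 0.001) {
  stopifnot(inherits(results, "screen_result"))
  if (is.null(decision)) decision <- fdr_threshold(results$p, q)
  unknown <- setdiff(prior_list, results$name)
  if (length(unknown))
    stop("unknown prior-hypothesis variable(s): ",
         paste(unknown, collapse = ", "))
  results$passes_fdr <- decision$pass
  results$route <- ifelse(decision$pass, "fdr", "none")
  pri <- results$name %in% prior_list & !decision$pass &
    results$p <= nominal_alpha
  results$passes_fdr[pri] <- TRUE
  results$route[pri] <- "prior"
  attr(results, "fdr") <- decision
  results
}
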