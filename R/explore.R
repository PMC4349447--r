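# Post-model probes of the final model: a pairwise interaction scan with a
# greedy reduction, quadratic non-linearity tests, mediator attenuation,
# and translation of an effect shift into a tail-prevalence change.

# design matrix of the final model's terms (plus partner status if needed)
final_design <- function(d, fit) {
  use_ps <- fit$includes_partner_status &&
    length(intersect(fit$terms, d$partner_vars)) > 0
  X <- d$C[, fit$terms, drop = FALSE]
  if (use_ps) X <- cbind(X, .partner_status. = d$ps)
  X
}

#' Pairwise interaction scan over a final model
#'
#' Tests every unordered pair of final-model variables by adding the product
#' of the two (standardized, un-recentred) columns to the full final model,
#' one pair at a time, so each interaction is adjusted for all main effects.
#' Product terms collinear with the mains (for example a binary variable
#' with itself coded identically) are skipped with a note. For each pair a
#' cell-mean grid of the outcome over the two variables' levels (continuous
#' variables binned into quintiles) is attached for plotting.
#'
#' @param fit final \code{model_fit} with at least 2 variables.
#' @param em the completed standardized \code{\link{exposome_matrix}}.
#' @param outcome numeric outcome vector.
#' @param p_crit significance criterion for flagging (default 0.001).
#' @param grids compute cell-mean grids (default TRUE; significant pairs
#'   only).
#' @return \code{data.frame} of class \code{interaction_scan} with one row
#'   per pair (\code{var1}, \code{var2}, \code{gamma}, \code{se},
#'   \code{ci_lo}, \code{ci_hi}, \code{p}, \code{significant},
#'   \code{skipped}); grids for significant pairs are in
#'   \code{attr(, "grids")}.
#' @export
interaction_scan <- function(fit, em, outcome, p_crit = 0.001,
                             grids = TRUE) {
  stopifnot(inherits(fit, "model_fit"))
  if (length(fit$terms) < 2)
    stop("interaction scan needs a final model with at least 2 variables")
  d <- prepare_selection(em, outcome, fit$terms)
  X <- final_design(d, fit)
  pairs <- utils::combn(fit$terms, 2)
  out <- data.frame(var1 = pairs[1, ], var2 = pairs[2, ],
                    gamma = NA_real_, se = NA_real_, ci_lo = NA_real_,
                    ci_hi = NA_real_, p = NA_real_, significant = FALSE,
                    skipped = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    prod_col <- d$C[, pairs[1, i]] * d$C[, pairs[2, i]]
    f <- ols(cbind(X, .interaction. = prod_col), d$y)
    if (".interaction." %in% f$aliased || stats::var(prod_col) == 0) {
      out$skipped[i] <- TRUE
      next
    }
    j <- ".interaction."
    out$gamma[i] <- f$coef[[j]]
    out$se[i] <- f$se[[j]]
    hw <- stats::qt(0.975, f$df) * f$se[[j]]
    out$ci_lo[i] <- f$coef[[j]] - hw
    out$ci_hi[i] <- f$coef[[j]] + hw
    out$p[i] <- f$p[[j]]
  }
  out$significant <- !out$skipped & out$p <= p_crit
  if (grids) {
    gl <- list()
    for (i in which(out$significant)) {
      gl[[paste(out$var1[i], out$var2[i], sep = ":")]] <-
        cell_mean_grid(d$C[, out$var1[i]], d$C[, out$var2[i]], d$y,
                       out$var1[i], out$var2[i])
    }
    attr(out, "grids") <- gl
  }
  attr(out, "p_crit") <- p_crit
  class(out) <- c("interaction_scan", "data.frame")
  out
}

# discretize a column to at most 5 ordered groups (observed levels if few,
# quintile bins otherwise), returning integer codes and labels
discretize5 <- function(x, max_groups = 5L) {
  ux <- sort(unique(x))
  if (length(ux) <= max_groups) {
    list(code = match(x, ux), labels = as.character(signif(ux, 4)))
  } else {
    br <- unique(stats::quantile(x, seq(0, 1, length.out = max_groups + 1)))
    code <- cut(x, br, include.lowest = TRUE, labels = FALSE)
    list(code = code, labels = paste0("Q", seq_len(length(br) - 1)))
  }
}

cell_mean_grid <- function(x1, x2, y, n1 = "var1", n2 = "var2") {
  d1 <- discretize5(x1); d2 <- discretize5(x2)
  mean_g <- tapply(y, list(d1$code, d2$code), mean)
  n_g <- table(factor(d1$code, seq_along(d1$labels)),
               factor(d2$code, seq_along(d2$labels)))
  dimnames(mean_g) <- list(d1$labels[as.integer(rownames(mean_g))],
                           d2$labels[as.integer(colnames(mean_g))])
  list(var1 = n1, var2 = n2, mean = mean_g, n = unclass(n_g))
}

#' Greedy reduction of a significant interaction set
#'
#' Adds the most significant interaction to the model, re-tests every other
#' significant interaction adjusted for the mains plus the chosen
#' interactions, drops those no longer significant, and repeats until no
#' remaining interaction qualifies. The explanation map records which
#' retained term absorbed each dropped one.
#'
#' @param interactions an \code{interaction_scan} result.
#' @param em,outcome,fit as in \code{\link{interaction_scan}}.
#' @param p_crit significance criterion (defaults to the scan's).
#' @return list with \code{retained} (data.frame of kept pairs with their
#'   final p-values), \code{explained} (map from dropped pair to the
#'   retained set that absorbed it).
#' @export
reduce_interactions <- function(interactions, em, outcome, fit,
                                p_crit = attr(interactions, "p_crit")) {
  sig <- interactions[which(interactions$significant), , drop = FALSE]
  if (!nrow(sig))
    return(list(retained = sig, explained = list()))
  d <- prepare_selection(em, outcome, fit$terms)
  X <- final_design(d, fit)
  prods <- sapply(seq_len(nrow(sig)), function(i)
    d$C[, sig$var1[i]] * d$C[, sig$var2[i]])
  colnames(prods) <- paste(sig$var1, sig$var2, sep = ":")
  active <- seq_len(nrow(sig))
  chosen <- integer(0)
  explained <- list()
  p_chosen <- numeric(0)
  while (length(active)) {
    pv <- vapply(active, function(i) {
      f <- ols(cbind(X, prods[, c(chosen, i), drop = FALSE]), d$y)
      f$p[[colnames(prods)[i]]]
    }, numeric(1))
    if (min(pv) > p_crit) break
    pick <- active[which.min(pv)]
    p_chosen <- c(p_chosen, min(pv))
    chosen <- c(chosen, pick)
    active <- setdiff(active, pick)
    if (length(active)) {
      pv2 <- vapply(active, function(i) {
        f <- ols(cbind(X, prods[, c(chosen, i), drop = FALSE]), d$y)
        f$p[[colnames(prods)[i]]]
      }, numeric(1))
      gone <- active[pv2 > p_crit]
      for (g in gone)
        explained[[colnames(prods)[g]]] <- colnames(prods)[chosen]
      active <- setdiff(active, gone)
    }
  }
  retained <- sig[match(chosen, seq_len(nrow(sig))), , drop = FALSE]
  retained$p_final <- p_chosen
  list(retained = retained, explained = explained)
}

#' Quadratic non-linearity tests
#'
#' Adds a squared term for each final-model variable, one at a time, to the
#' full final model. Variables with fewer than three distinct observed
#' levels (binary variables) cannot support a quadratic term and are
#' returned as untestable.
#'
#' @param fit final \code{model_fit}.
#' @param em,outcome data.
#' @param p_crit flag criterion (default 0.001).
#' @return data.frame with \code{term}, \code{gamma2}, \code{p},
#'   \code{testable}, \code{significant}.
#' @export
quadratic_tests <- function(fit, em, outcome, p_crit = 0.001) {
  d <- prepare_selection(em, outcome, fit$terms)
  X <- final_design(d, fit)
  out <- data.frame(term = fit$terms, gamma2 = NA_real_, p = NA_real_,
                    testable = NA, significant = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(fit$terms)) {
    x <- d$C[, fit$terms[i]]
    if (length(unique(x)) < 3) {
      out$testable[i] <- FALSE
      next
    }
    out$testable[i] <- TRUE
    f <- ols(cbind(X, .quadratic. = x^2), d$y)
    if (".quadratic." %in% f$aliased) {
      out$testable[i] <- FALSE
      next
    }
    out$gamma2[i] <- f$coef[[".quadratic."]]
    out$p[i] <- f$p[[".quadratic."]]
  }
  out$significant <- !is.na(out$p) & out$p <= p_crit
  out
}

#' Mediator attenuation analysis
#'
#' Refits the final model with candidate mediators added and reports, per
#' exposure, the percentage attenuation of its coefficient,
#' 100 (1 - B_with / B_without), flagging exposures whose adjusted effect is
#' consistent with zero. The share of the model's total explanation running
#' through the mediators is the relative drop in the exposure-attributable
#' R-squared: 1 minus the exposure semi-partial increment over the
#' mediators, relative to the exposure-only R-squared.
#'
#' @param fit final \code{model_fit}.
#' @param em,outcome data.
#' @param mediators named numeric matrix (or vector) of mediator columns,
#'   rows aligned with subjects.
#' @param alpha level for the "consistent with no direct effect" flag
#'   (default 0.05).
#' @return object of class \code{mediation_result}: list with \code{table}
#'   (term, B_without, B_with, attenuation_pct, p_with, no_direct_effect,
#'   sign_flip), \code{share_mediated_pct}, \code{r2_without},
#'   \code{r2_with_mediators}.
#' @export
mediation_analysis <- function(fit, em, outcome, mediators, alpha = 0.05) {
  if (is.null(dim(mediators)))
    mediators <- matrix(mediators, ncol = 1,
                        dimnames = list(NULL, "mediator"))
  mediators <- as.matrix(mediators)
  if (is.null(colnames(mediators)))
    colnames(mediators) <- paste0("mediator", seq_len(ncol(mediators)))
  if (any(colnames(mediators) %in% fit$terms))
    stop("mediator shares a name with a model variable")
  rows <- which(!is.na(outcome))
  Mm <- mediators[rows, , drop = FALSE]
  d <- prepare_selection(em, outcome, fit$terms)
  X <- final_design(d, fit)
  if (any(vapply(seq_len(ncol(Mm)), function(j)
    any(vapply(seq_len(ncol(X)), function(i)
      isTRUE(all.equal(X[, i], Mm[, j])), logical(1))), logical(1))))
    stop("a mediator is identical to a model variable")
  f0 <- ols(X, d$y)
  f1 <- ols(cbind(X, Mm), d$y)
  fm <- ols(Mm, d$y)
  b0 <- f0$coef[fit$terms]
  b1 <- f1$coef[fit$terms]
  att <- 100 * (1 - b1 / b0)
  tab <- data.frame(term = fit$terms, B_without = b0, B_with = b1,
                    attenuation_pct = att,
                    p_with = f1$p[fit$terms],
                    no_direct_effect = f1$p[fit$terms] > alpha,
                    sign_flip = sign(b1) * sign(b0) < 0,
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  r2_without <- f0$r_squared
  exposure_increment <- f1$r_squared - fm$r_squared
  share <- 100 * (1 - exposure_increment / r2_without)
  structure(list(table = tab, share_mediated_pct = share,
                 r2_without = r2_without,
                 r2_with_mediators = f1$r_squared, alpha = alpha),
            class = "mediation_result")
}

#' Tail-prevalence shift for an outcome change
#'
#' Defines impairment as the worst \code{tail_fraction} of the population
#' outcome distribution (cutoff at that quantile) and returns the fraction
#' of the population that would fall below the fixed cutoff if every score
#' shifted by \code{delta}: F(cutoff - delta). A beneficial shift
#' (\code{delta > 0}, higher scores) shrinks the tail; a detrimental shift
#' grows it; \code{delta = 0} returns exactly \code{tail_fraction}.
#'
#' @param outcome numeric outcome sample (empirical distribution), or for
#'   \code{distribution = "normal"} the mean and sd may be given directly
#'   via \code{mean}/\code{sd} with \code{outcome = NULL}.
#' @param delta shift in outcome units.
#' @param tail_fraction the impaired tail (default 0.10, the worst 10\%).
#' @param distribution \code{"empirical"} (type-1 empirical quantile and
#'   ECDF) or \code{"normal"} (closed form).
#' @param mean,sd normal parameters (estimated from \code{outcome} when not
#'   supplied).
#' @return shifted tail prevalence (a proportion).
#' @export
prevalence_shift <- function(outcome, delta, tail_fraction = 0.10,
                             distribution = c("empirical", "normal"),
                             mean = NULL, sd = NULL) {
  distribution <- match.arg(distribution)
  stopifnot(tail_fraction > 0, tail_fraction < 1)
  if (distribution == "normal") {
    if (is.null(mean)) mean <- base::mean(outcome)
    if (is.null(sd)) sd <- stats::sd(outcome)
    cutoff <- stats::qnorm(tail_fraction, mean, sd)
    return(stats::pnorm(cutoff - delta, mean, sd))
  }
  y <- outcome[!is.na(outcome)]
  if (abs(delta) > diff(range(y)))
    stop("delta exceeds the outcome range")
  cutoff <- stats::quantile(y, tail_fraction, type = 1, names = FALSE)
  base::mean(y <= cutoff - delta)
}
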