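# Sensitivity analyses for the final model: a proportional-odds refit that
# relaxes the normality assumption, selection in an orthogonal factor space,
# a CHAID-style regression tree that admits non-linearity and interactions,
# and a cross-method consistency report.

#' Proportional-odds refit of the final model
#'
#' Discretizes the near-continuous outcome into equal-frequency categories
#' (default 20) and refits the final model's variables as an ordinal
#' logistic (proportional-odds) regression. Odds ratios are oriented so
#' that OR > 1 means a beneficial effect (higher outcome), matching the
#' sign convention of the linear coefficients. The log-likelihood
#' explanation is McFadden's pseudo-R-squared, 1 - LL(model)/LL(null).
#' Non-convergence triggers a fall-back to coarser binning (10, then 5).
#'
#' @param fit final \code{model_fit}.
#' @param em completed standardized \code{\link{exposome_matrix}}.
#' @param outcome numeric outcome vector.
#' @param n_bins outcome categories (default 20 equal-frequency bins).
#' @return object of class \code{ordinal_fit}: list with \code{table}
#'   (term, OR, ci_lo, ci_hi, log_or, p), \code{pseudo_r2},
#'   \code{linear_r2}, \code{n_bins_used}, \code{rank_concordance}
#'   (Spearman correlation of |B| and |log OR| ranks) and
#'   \code{max_rank_shift}.
#' @export
ordinal_refit <- function(fit, em, outcome, n_bins = 20) {
  stopifnot(inherits(fit, "model_fit"), length(fit$terms) >= 1)
  d <- prepare_selection(em, outcome, fit$terms)
  X <- final_design(d, fit)
  for (nb in unique(c(n_bins, 10, 5))) {
    br <- unique(stats::quantile(d$y, seq(0, 1, length.out = nb + 1)))
    yo <- cut(d$y, br, include.lowest = TRUE, ordered_result = TRUE)
    if (nlevels(droplevels(yo)) < 3) next
    df <- data.frame(.y. = yo, X, check.names = FALSE)
    pf <- tryCatch(
      suppressWarnings(MASS::polr(.y. ~ ., data = df, Hess = TRUE,
                                  method = "logistic")),
      error = function(e) NULL)
    if (!is.null(pf) && pf$convergence == 0) {
      return(build_ordinal_fit(pf, fit, yo, nb))
    }
  }
  stop("proportional-odds refit failed to converge at any binning")
}

build_ordinal_fit <- function(pf, fit, yo, nb) {
  cf <- pf$coefficients          # positive = higher outcome more likely
  vc <- stats::vcov(pf)
  se <- sqrt(diag(vc)[names(cf)])
  z <- cf / se
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  tab <- data.frame(term = names(cf), OR = exp(cf),
                    ci_lo = exp(cf - 1.96 * se),
                    ci_hi = exp(cf + 1.96 * se),
                    log_or = cf, se_log_or = se, p = p,
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  counts <- table(yo)
  counts <- counts[counts > 0]
  ll0 <- sum(counts * log(counts / sum(counts)))
  ll <- as.numeric(stats::logLik(pf))
  shared <- intersect(fit$terms, tab$term)
  rb <- rank(-abs(fit$table$B[match(shared, fit$table$term)]))
  ro <- rank(-abs(tab$log_or[match(shared, tab$term)]))
  structure(list(table = tab, pseudo_r2 = 1 - ll / ll0,
                 linear_r2 = fit$r_squared, n_bins_used = nb,
                 rank_concordance = if (length(shared) > 1)
                   stats::cor(rb, ro, method = "spearman") else NA_real_,
                 max_rank_shift = if (length(shared) > 1)
                   max(abs(rb - ro)) else NA_real_,
                 orientation = "B>0 and OR>1 are beneficial effects"),
            class = "ordinal_fit")
}

#' @export
print.ordinal_fit <- function(x, ...) {
  cat(sprintf(
    "ordinal_fit: %d terms, %d outcome bins, pseudo-R^2 = %.4f (linear R^2 = %.4f)\n",
    nrow(x$table), x$n_bins_used, x$pseudo_r2, x$linear_r2))
  cat(" ", x$orientation, "\n")
  tab <- x$table
  tab$OR <- round(tab$OR, 3)
  print(tab[, c("term", "OR", "p")], row.names = FALSE)
  invisible(x)
}

#' Factor-space sensitivity analysis
#'
#' Replaces the correlated stage-1 survivors by orthogonal derived
#' variables: principal factors of the correlation matrix (retained while
#' the eigenvalue exceeds 1), varimax-rotated, with unit-variance
#' uncorrelated scores. Stepwise selection is then run on the factor scores
#' and each selected factor is attributed to the variable with its largest
#' absolute loading, giving an overlap report against the variable-level
#' final model.
#'
#' @param em completed standardized \code{\link{exposome_matrix}} restricted
#'   to the stage-1 survivors.
#' @param outcome numeric outcome vector.
#' @param p_crit selection criterion for factor scores.
#' @param method stepwise method on the scores (default forwards; the
#'   scores are orthogonal so all methods agree).
#' @param final_fit optional variable-level \code{model_fit} for the
#'   overlap report.
#' @return list with \code{loadings}, \code{n_factors}, \code{scores_fit}
#'   (a \code{model_fit} on factor scores), \code{attribution} (factor to
#'   top-loading variable) and \code{overlap} (attributed variables also in
#'   the final model).
#' @export
factor_sensitivity <- function(em, outcome, p_crit, method = "forwards",
                               final_fit = NULL) {
  rows <- which(!is.na(outcome))
  Z <- em$data[rows, , drop = FALSE]
  if (anyNA(Z)) stop("factor extraction needs completed (imputed) data")
  y <- outcome[rows]
  n <- nrow(Z); m <- ncol(Z)
  if (m > n)
    warning("more variables than subjects; factor extraction on a ",
            "reduced-rank correlation matrix")
  Zs <- base::scale(Z)
  R <- stats::cor(Z)
  eg <- eigen(R, symmetric = TRUE)
  nf <- max(1L, sum(eg$values > 1))
  L <- eg$vectors[, seq_len(nf), drop = FALSE] %*%
    diag(sqrt(eg$values[seq_len(nf)]), nf)
  rot <- if (nf > 1) stats::varimax(L) else list(loadings = L,
                                                 rotmat = diag(1))
  Lr <- unclass(rot$loadings)
  dimnames(Lr) <- list(colnames(Z), paste0("F", seq_len(nf)))
  # unit-variance orthogonal scores; an orthogonal rotation keeps them so
  scores <- Zs %*% eg$vectors[, seq_len(nf), drop = FALSE] %*%
    diag(1 / sqrt(eg$values[seq_len(nf)]), nf) %*% rot$rotmat
  colnames(scores) <- colnames(Lr)

  fd <- list(y = y, C = scores, ps = em$partner_status[rows],
             partner_vars = character(0))
  sf <- switch(method,
               subset = list(fit = best_subset_search_engine(
                 fd, colnames(scores), p_crit)),
               forwards = forwards_engine(fd, colnames(scores), p_crit),
               backwards = backwards_engine(fd, colnames(scores), p_crit))
  attribution <- vapply(colnames(Lr), function(f)
    rownames(Lr)[which.max(abs(Lr[, f]))], character(1))
  sel <- sf$fit$terms
  overlap <- if (!is.null(final_fit))
    intersect(unname(attribution[sel]), final_fit$terms) else NULL
  list(loadings = Lr, n_factors = nf, scores = scores,
       scores_fit = sf$fit, attribution = attribution, overlap = overlap)
}

#' CHAID-style regression tree
#'
#' Recursive partitioning of a continuous outcome adapted from chi-squared
#' automatic interaction detection: at each node, each predictor's ordered
#' categories (continuous predictors pre-binned into quintiles) are merged
#' stepwise while the pairwise F-test between adjacent categories is
#' non-significant; the best predictor is chosen by its
#' Bonferroni-adjusted one-way ANOVA p-value (multiplier = number of ways
#' to merge the original categories into the final groups) and the node is
#' split if the adjusted p is below \code{alpha_split} and every child
#' holds at least \code{min_leaf} subjects. Non-linear associations appear
#' as multi-way branches and interactions as the tree hierarchy.
#'
#' @param em completed standardized \code{\link{exposome_matrix}} of the
#'   candidate predictors (typically the stage-1 survivors or final-model
#'   variables).
#' @param outcome numeric outcome vector.
#' @param alpha_split split criterion on the adjusted p (default 0.001).
#' @param min_leaf minimum child size (default 50).
#' @param merge_alpha category-merging criterion (default 0.05).
#' @param max_depth recursion cap (default 5).
#' @return object of class \code{chaid_tree}: nested node list; leaves
#'   carry the mean outcome and size.
#' @export
chaid_tree <- function(em, outcome, alpha_split = 0.001, min_leaf = 50,
                       merge_alpha = 0.05, max_depth = 5) {
  rows <- which(!is.na(outcome))
  X <- em$data[rows, , drop = FALSE]
  if (anyNA(X)) stop("tree construction needs completed (imputed) data")
  y <- outcome[rows]
  cats <- lapply(seq_len(ncol(X)), function(j) discretize5(X[, j])$code)
  names(cats) <- colnames(X)
  node <- grow_chaid(cats, y, seq_along(y), alpha_split, min_leaf,
                     merge_alpha, max_depth, depth = 0)
  structure(list(root = node, alpha_split = alpha_split,
                 min_leaf = min_leaf, n = length(y)),
            class = "chaid_tree")
}

# pairwise F test (equal-variance two-group ANOVA) between two outcome
# groups; returns the p-value
pair_f_p <- function(y1, y2) {
  n1 <- length(y1); n2 <- length(y2)
  if (n1 < 2 || n2 < 2) return(1)
  mg <- (sum(y1) + sum(y2)) / (n1 + n2)
  ssb <- n1 * (mean(y1) - mg)^2 + n2 * (mean(y2) - mg)^2
  ssw <- sum((y1 - mean(y1))^2) + sum((y2 - mean(y2))^2)
  df2 <- n1 + n2 - 2
  if (ssw <= 0) return(if (ssb > 0) 0 else 1)
  stats::pf(ssb / (ssw / df2), 1, df2, lower.tail = FALSE)
}

# merge ordered categories while adjacent pairs are non-significant;
# returns group assignment per original category and the merge count
merge_categories <- function(codes, y, merge_alpha) {
  lev <- sort(unique(codes))
  groups <- as.list(lev)
  repeat {
    if (length(groups) <= 2) break
    pv <- vapply(seq_len(length(groups) - 1), function(i) {
      pair_f_p(y[codes %in% groups[[i]]], y[codes %in% groups[[i + 1]]])
    }, numeric(1))
    i <- which.max(pv)
    if (pv[i] <= merge_alpha) break
    groups[[i]] <- c(groups[[i]], groups[[i + 1]])
    groups <- groups[-(i + 1)]
  }
  groups
}

grow_chaid <- function(cats, y, idx, alpha_split, min_leaf, merge_alpha,
                       max_depth, depth) {
  node <- list(n = length(idx), mean = mean(y[idx]), leaf = TRUE)
  if (depth >= max_depth || length(idx) < 2 * min_leaf) return(node)
  best <- NULL
  for (v in names(cats)) {
    codes <- cats[[v]][idx]
    c_orig <- length(unique(codes))
    if (c_orig < 2) next
    groups <- merge_categories(codes, y[idx], merge_alpha)
    kk <- length(groups)
    if (kk < 2) next
    g <- integer(length(codes))
    for (i in seq_along(groups)) g[codes %in% groups[[i]]] <- i
    if (any(tabulate(g, kk) < min_leaf)) next
    # one-way ANOVA across merged groups
    an <- stats::anova(stats::lm(y[idx] ~ factor(g)))
    p_raw <- an$`Pr(>F)`[1]
    mult <- choose(c_orig - 1, kk - 1)       # ordinal merge multiplicity
    p_adj <- min(1, p_raw * mult)
    if (is.null(best) || p_adj < best$p_adj)
      best <- list(var = v, groups = groups, g = g, p_adj = p_adj,
                   F = an$`F value`[1])
  }
  if (is.null(best) || best$p_adj > alpha_split) return(node)
  node$leaf <- FALSE
  node$split_var <- best$var
  node$p_adj <- best$p_adj
  node$F <- best$F
  node$groups <- best$groups
  node$children <- lapply(seq_along(best$groups), function(i) {
    grow_chaid(cats, y, idx[best$g == i], alpha_split, min_leaf,
               merge_alpha, max_depth, depth + 1)
  })
  node
}

#' @export
print.chaid_tree <- function(x, ...) {
  cat("CHAID-style regression tree (alpha_split =", x$alpha_split,
      ", min_leaf =", x$min_leaf, ")\n")
  print_chaid_node(x$root, indent = "")
  invisible(x)
}

print_chaid_node <- function(node, indent) {
  if (node$leaf) {
    cat(indent, sprintf("leaf: n = %d, mean = %.2f\n", node$n, node$mean))
  } else {
    cat(indent, sprintf("split on %s (adj p = %.3g)\n", node$split_var,
                        node$p_adj))
    for (i in seq_along(node$children)) {
      cat(indent, sprintf(" categories {%s}:\n",
                          paste(node$groups[[i]], collapse = ",")))
      print_chaid_node(node$children[[i]], paste0(indent, "   "))
    }
  }
}

# collect leaves of a chaid tree as a data.frame
chaid_leaves <- function(tree) {
  acc <- list()
  walk <- function(node, path) {
    if (node$leaf) {
      acc[[length(acc) + 1]] <<- data.frame(path = path, n = node$n,
                                            mean = node$mean)
    } else {
      for (i in seq_along(node$children))
        walk(node$children[[i]],
             paste0(path, "/", node$split_var, ":",
                    paste(node$groups[[i]], collapse = ",")))
    }
  }
  walk(tree$root, "")
  do.call(rbind, acc)
}

# flat edge list (parent, child, split variable, categories) for export
chaid_edges <- function(tree) {
  acc <- list()
  counter <- 0L
  walk <- function(node, parent_id) {
    counter <<- counter + 1L
    my_id <- counter
    acc[[length(acc) + 1]] <<- data.frame(
      node = my_id, parent = parent_id,
      split_var = if (node$leaf) NA_character_ else node$split_var,
      p_adj = if (node$leaf) NA_real_ else node$p_adj,
      n = node$n, mean = node$mean, leaf = node$leaf)
    if (!node$leaf)
      for (ch in node$children) walk(ch, my_id)
  }
  walk(tree$root, 0L)
  do.call(rbind, acc)
}

#' Cross-method consistency report
#'
#' Compares two or more fitted models (for example forwards vs backwards vs
#' subset selections): pairwise Jaccard overlap of the variable sets,
#' per-variable inclusion frequency, an R-squared comparison, and flags for
#' variables selected by exactly one method.
#'
#' @param fits named list of \code{model_fit} objects (length >= 2).
#' @return list with \code{jaccard} (matrix), \code{inclusion}
#'   (data.frame: term, frequency, methods), \code{r_squared} (named
#'   vector) and \code{unique_to_one} (character).
#' @export
consistency_report <- function(fits) {
  stopifnot(length(fits) >= 2, !is.null(names(fits)))
  sets <- lapply(fits, function(f) f$terms)
  k <- length(sets)
  J <- matrix(1, k, k, dimnames = list(names(fits), names(fits)))
  for (i in seq_len(k - 1)) for (j in seq.int(i + 1, k)) {
    u <- length(union(sets[[i]], sets[[j]]))
    J[i, j] <- J[j, i] <- if (u == 0) 1 else
      length(intersect(sets[[i]], sets[[j]])) / u
  }
  all_terms <- unique(unlist(sets))
  inc <- data.frame(
    term = all_terms,
    frequency = vapply(all_terms, function(t)
      mean(vapply(sets, function(s) t %in% s, logical(1))), numeric(1)),
    methods = vapply(all_terms, function(t)
      paste(names(fits)[vapply(sets, function(s) t %in% s, logical(1))],
            collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  rownames(inc) <- NULL
  list(jaccard = J,
       inclusion = inc[order(-inc$frequency, inc$term), ],
       r_squared = vapply(fits, function(f) f$r_squared, numeric(1)),
       unique_to_one = inc$term[inc$frequency == 1 / k])
}
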