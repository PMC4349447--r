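# Stages 2-3 of the scan: multivariable reduction of the stage-1 survivors
# by forwards, backwards and best-subset ("subset stepwise") regression,
# using one significance criterion for both inclusion and removal; partial
# correlation ranking; attenuation summaries.

model_fit <- function(terms, olsfit, labels, method, p_crit,
                      partner_included, trace = NULL, empty = FALSE,
                      aliased = character(0)) {
  tab <- data.frame(term = labels, B = olsfit$coef[labels],
                    se = olsfit$se[labels], stringsAsFactors = FALSE)
  hw <- stats::qt(0.975, olsfit$df) * tab$se
  tab$ci_lo <- tab$B - hw
  tab$ci_hi <- tab$B + hw
  tab$t <- olsfit$t[labels]
  tab$p <- olsfit$p[labels]
  tab$partial_r <- sign(tab$t) *
    sqrt(tab$t^2 / (tab$t^2 + olsfit$df))
  rownames(tab) <- NULL
  structure(list(terms = terms, table = tab,
                 r_squared = olsfit$r_squared, n = olsfit$n, df = olsfit$df,
                 intercept = olsfit$coef[["(Intercept)"]],
                 fitted = olsfit$fitted,
                 method = method, p_crit = p_crit,
                 includes_partner_status = partner_included,
                 trace = trace, empty = empty, aliased = aliased),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("model_fit (%s): %d variable(s), R^2 = %.4f, n = %d%s\n",
              x$method, length(x$terms), x$r_squared, x$n,
              if (x$includes_partner_status) " (+ partner status)" else ""))
  if (x$empty) cat("  [intercept-only: no admissible variable]\n")
  if (nrow(x$table)) {
    tab <- x$table
    tab$B <- round(tab$B, 3); tab$se <- round(tab$se, 3)
    tab$partial_r <- round(tab$partial_r, 3)
    print(tab[order(-abs(tab$partial_r)),
              c("term", "B", "se", "p", "partial_r")], row.names = FALSE)
  }
  invisible(x)
}

# assemble the analysis design pieces for a candidate set
prepare_selection <- function(em, outcome, candidates) {
  rows <- which(!is.na(outcome))
  idx <- match(candidates, colnames(em$data))
  if (anyNA(idx)) stop("unknown candidate variable(s): ",
                       paste(candidates[is.na(idx)], collapse = ", "))
  C <- em$data[rows, idx, drop = FALSE]
  if (anyNA(C))
    stop("candidate columns contain missing values; run mice_impute() ",
         "(or restrict to complete data) before selection")
  ps <- em$partner_status[rows]
  partner_vars <- candidates[em$codebook$reporter[idx] == "partner"]
  if (stats::var(ps) == 0) partner_vars <- character(0)  # ps uninformative
  list(y = outcome[rows], C = C, ps = ps, partner_vars = partner_vars)
}

fit_terms <- function(d, terms, method, p_crit, trace = NULL,
                      empty = FALSE) {
  use_ps <- length(intersect(terms, d$partner_vars)) > 0
  X <- d$C[, terms, drop = FALSE]
  if (use_ps) X <- cbind(X, .partner_status. = d$ps)
  f <- ols(if (ncol(X)) X else NULL, d$y)
  labels <- c(terms, if (use_ps) ".partner_status.")
  model_fit(terms, f, labels, method, p_crit, use_ps, trace = trace,
            empty = empty || length(terms) == 0, aliased = f$aliased)
}

#' Refit a variable set as a model_fit
#'
#' Plain OLS of the outcome on the given (standardized) variables, with
#' partner status auto-included when any variable is partner-reported. Used
#' to re-estimate a selected model on each completed dataset before pooling.
#'
#' @param em a completed standardized \code{\link{exposome_matrix}}.
#' @param outcome numeric outcome vector.
#' @param terms variable names to fit.
#' @param p_crit criterion recorded on the fit (not enforced).
#' @return a \code{model_fit}.
#' @export
refit_model <- function(em, outcome, terms, p_crit = NA_real_) {
  d <- prepare_selection(em, outcome, terms)
  fit_terms(d, terms, "refit", p_crit)
}

#' Stepwise selection under a single significance criterion
#'
#' Forwards: repeatedly add the candidate with the smallest partial-F
#' p-value while it is below \code{p_crit}. Backwards: start from the full
#' candidate model and repeatedly remove the largest-p variable above
#' \code{p_crit}. Subset: delegate to \code{\link{best_subset_search}}.
#' One threshold serves as both the entry and removal criterion, the natural
#' reading of a single FDR-derived criterion for inclusion or removal.
#' Partner status is auto-included whenever a partner-reported variable is
#' in the working set; it never counts against model size and is exempt
#' from the significance filter. Ties on p-values are broken by candidate
#' order and recorded in the trace. Aliased (perfectly collinear) variables
#' in a backwards full model are removed first and reported.
#'
#' @param em a completed standardized \code{\link{exposome_matrix}}.
#' @param outcome numeric outcome vector (NA = excluded subject).
#' @param candidates character vector of candidate variable names.
#' @param method \code{"forwards"}, \code{"backwards"} or \code{"subset"}.
#' @param p_crit significance criterion for inclusion/removal (typically the
#'   stage-1 FDR nominal critical value).
#' @param ... passed to \code{\link{best_subset_search}} for
#'   \code{method = "subset"}.
#' @return list with \code{fit} (a \code{model_fit}) and \code{trace}
#'   (a data.frame log of add/remove steps with the p-value justifying each).
#' @export
stepwise_fit <- function(em, outcome, candidates,
                         method = c("forwards", "backwards", "subset"),
                         p_crit, ...) {
  method <- match.arg(method)
  stopifnot(is.numeric(p_crit), p_crit > 0, p_crit < 1)
  if (!length(candidates)) {
    d <- prepare_selection(em, outcome, character(0))
    fit <- fit_terms(d, character(0), method, p_crit, empty = TRUE)
    return(list(fit = fit, trace = empty_trace()))
  }
  d <- prepare_selection(em, outcome, candidates)
  switch(method,
         forwards = forwards_engine(d, candidates, p_crit),
         backwards = backwards_engine(d, candidates, p_crit),
         subset = {
           fit <- best_subset_search_engine(d, candidates, p_crit, ...)
           tr <- empty_trace()
           if (length(fit$terms))
             tr <- data.frame(step = seq_along(fit$terms), action = "add",
                              variable = fit$terms,
                              p = fit$table$p[match(fit$terms,
                                                    fit$table$term)],
                              tie = FALSE, stringsAsFactors = FALSE)
           fit$trace <- tr
           list(fit = fit, trace = tr)
         })
}

empty_trace <- function() {
  data.frame(step = integer(0), action = character(0),
             variable = character(0), p = numeric(0), tie = logical(0),
             stringsAsFactors = FALSE)
}

# partial p-value of every remaining candidate given the current model,
# computed by residualizing candidates and outcome on the current design
partial_pvalues <- function(d, current, remaining) {
  use_ps_base <- length(intersect(current, d$partner_vars)) > 0
  base <- cbind(rep(1, length(d$y)), d$C[, current, drop = FALSE],
                if (use_ps_base) d$ps)
  qb <- qr(base)
  partner_rem <- remaining %in% d$partner_vars
  pv <- numeric(length(remaining))
  compute_block <- function(qrb, vars) {
    ry <- qr.resid(qrb, d$y)
    RC <- qr.resid(qrb, d$C[, vars, drop = FALSE])
    df <- length(d$y) - qrb$rank - 1
    ss <- colSums(RC^2)
    r <- ifelse(ss > 1e-10, colSums(RC * ry) / sqrt(ss * sum(ry^2)), 0)
    r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
    tt <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
    p[ss <= 1e-10] <- 1  # candidate collinear with current model
    p
  }
  if (any(!partner_rem))
    pv[!partner_rem] <- compute_block(qb, remaining[!partner_rem])
  if (any(partner_rem)) {
    if (use_ps_base) {
      pv[partner_rem] <- compute_block(qb, remaining[partner_rem])
    } else {
      qb2 <- qr(cbind(base, d$ps))
      pv[partner_rem] <- compute_block(qb2, remaining[partner_rem])
    }
  }
  pv
}

forwards_engine <- function(d, candidates, p_crit) {
  current <- character(0)
  remaining <- candidates
  tr <- empty_trace()
  step <- 0L
  while (length(remaining)) {
    pv <- partial_pvalues(d, current, remaining)
    best <- min(pv)
    if (best > p_crit) break
    hit <- which(pv <= best + 1e-300 & abs(pv - best) < 1e-12)
    pick <- hit[1]                      # tie broken by candidate order
    step <- step + 1L
    tr <- rbind(tr, data.frame(step = step, action = "add",
                               variable = remaining[pick], p = best,
                               tie = length(hit) > 1))
    current <- c(current, remaining[pick])
    remaining <- remaining[-pick]
  }
  fit <- fit_terms(d, current, "forwards", p_crit, trace = tr,
                   empty = length(current) == 0)
  list(fit = fit, trace = tr)
}

backwards_engine <- function(d, candidates, p_crit) {
  current <- candidates
  tr <- empty_trace()
  step <- 0L
  aliased_all <- character(0)
  repeat {
    f <- fit_terms(d, current, "backwards", p_crit)
    al <- intersect(f$aliased, current)
    if (length(al)) {                   # singular full model: drop aliased
      step <- step + 1L
      tr <- rbind(tr, data.frame(step = step, action = "remove_aliased",
                                 variable = al[length(al)], p = NA_real_,
                                 tie = FALSE))
      aliased_all <- c(aliased_all, al[length(al)])
      current <- setdiff(current, al[length(al)])
      next
    }
    if (!length(current)) break
    pv <- f$table$p[match(current, f$table$term)]
    worst <- max(pv)
    if (worst <= p_crit || !length(current)) break
    hit <- which(abs(pv - worst) < 1e-12)
    pick <- hit[length(hit)]            # tie: later candidate leaves first
    step <- step + 1L
    tr <- rbind(tr, data.frame(step = step, action = "remove",
                               variable = current[pick], p = worst,
                               tie = length(hit) > 1))
    current <- current[-pick]
  }
  fit <- fit_terms(d, current, "backwards", p_crit, trace = tr,
                   empty = length(current) == 0)
  fit$aliased <- aliased_all
  list(fit = fit, trace = tr)
}

#' Best-subset ("subset stepwise") search
#'
#' Searches over subsets of the candidates for the model with maximal
#' R-squared among subsets whose every member satisfies \code{p <= p_crit}
#' in the joint fit (partner status exempt). For at most
#' \code{max_exhaustive} candidates the search enumerates all subsets and is
#' exact; above that, a depth-first branch-and-bound prunes any branch whose
#' unconstrained completion RSS (a lower bound for every subset in the
#' branch) cannot beat the best admissible subset found so far, so the
#' result equals the exhaustive optimum in both regimes. If no subset is
#' admissible the intercept-only model is returned with an explicit flag.
#'
#' @param em a completed standardized \code{\link{exposome_matrix}}.
#' @param outcome numeric outcome vector.
#' @param candidates candidate variable names.
#' @param p_crit significance criterion every member must meet.
#' @param max_exhaustive exhaustive-enumeration bound (default 15).
#' @return a \code{model_fit} with method tag \code{"subset"}.
#' @export
best_subset_search <- function(em, outcome, candidates, p_crit,
                               max_exhaustive = 15) {
  d <- prepare_selection(em, outcome, candidates)
  best_subset_search_engine(d, candidates, p_crit, max_exhaustive)
}

best_subset_search_engine <- function(d, candidates, p_crit,
                                      max_exhaustive = 15) {
  k <- length(candidates)
  n <- length(d$y)
  has_partner <- length(d$partner_vars) > 0
  # augmented Gram: [1, ps, C] x [1, ps, C, y]
  A <- cbind(1, if (has_partner) d$ps, d$C)
  colnames(A) <- c("(Intercept)", if (has_partner) ".partner_status.",
                   candidates)
  G <- crossprod(A)
  gy <- crossprod(A, d$y)
  yty <- sum(d$y^2)
  sy <- sum(d$y); tss <- yty - sy^2 / n
  ps_col <- if (has_partner) 2L else NA_integer_
  off <- if (has_partner) 2L else 1L
  is_pvar <- candidates %in% d$partner_vars

  # evaluate subset given candidate indices; returns NULL if singular
  eval_subset <- function(sel) {
    use_ps <- has_partner && any(is_pvar[sel])
    cols <- c(1L, if (use_ps) ps_col, sel + off)
    Gm <- G[cols, cols, drop = FALSE]
    ch <- tryCatch(chol(Gm), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    b <- backsolve(ch, forwardsolve(t(ch), gy[cols]))
    rss <- max(yty - sum(b * gy[cols]), 0)
    df <- n - length(cols)
    list(sel = sel, rss = rss, df = df, use_ps = use_ps, chol = ch, b = b,
         cols = cols)
  }
  admissible <- function(ev) {
    if (is.null(ev) || !length(ev$sel)) return(!is.null(ev))
    if (ev$df <= 0) return(FALSE)
    xtxinv <- chol2inv(ev$chol)
    se <- sqrt(pmax(diag(xtxinv), 0) * ev$rss / ev$df)
    tt <- ev$b / se
    # members only: skip intercept (and ps) positions
    memb <- seq_along(ev$cols) > (1 + ev$use_ps)
    pv <- 2 * stats::pt(abs(tt[memb]), ev$df, lower.tail = FALSE)
    all(pv <= p_crit)
  }

  best <- NULL
  consider <- function(ev) {
    if (is.null(ev)) return()
    if (is.null(best) || ev$rss < best$rss - 1e-10 ||
        (abs(ev$rss - best$rss) <= 1e-10 &&
         length(ev$sel) < length(best$sel)))
      best <<- ev
  }

  if (k <= max_exhaustive) {
    for (mask in seq_len(2^k - 1)) {
      sel <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
      ev <- eval_subset(sel)
      if (admissible(ev)) consider(ev)
    }
  } else {
    # Exact branch-and-bound on the constrained objective: prune a branch
    # when even the unconstrained fit on included-plus-all-remaining
    # variables cannot beat the best admissible subset found so far (the
    # unconstrained RSS is a lower bound for every completion). Candidates
    # are ordered by decreasing marginal correlation and the search is
    # seeded with a greedy admissible solution so pruning engages early.
    r_marg <- abs(gy[seq_len(k) + off] - G[seq_len(k) + off, 1] * sy / n)
    ord <- order(r_marg / sqrt(pmax(diag(G)[seq_len(k) + off] -
                                      G[seq_len(k) + off, 1]^2 / n, 1e-12)),
                 decreasing = TRUE)
    rss_of <- function(sel) {
      ev <- eval_subset(sel)
      if (is.null(ev)) Inf else ev$rss
    }
    # greedy seed: grow by best RSS reduction, keep best admissible prefix
    inc <- integer(0); avail <- ord
    while (length(avail)) {
      rs <- vapply(avail, function(v) rss_of(c(inc, v)), numeric(1))
      v <- avail[which.min(rs)]
      inc <- c(inc, v); avail <- setdiff(avail, v)
      ev <- eval_subset(inc)
      if (admissible(ev)) consider(ev)
    }
    best_rss <- if (is.null(best)) Inf else best$rss
    dfs <- function(inc, pos) {
      if (pos > k) return()
      if (rss_of(c(inc, ord[pos:k])) >= best_rss) return()
      inc2 <- c(inc, ord[pos])
      ev <- eval_subset(inc2)
      if (!is.null(ev) && ev$rss < best_rss && admissible(ev)) {
        consider(ev)
        best_rss <<- best$rss
      }
      dfs(inc2, pos + 1L)
      dfs(inc, pos + 1L)
    }
    dfs(integer(0), 1L)
  }

  terms <- if (is.null(best)) character(0) else candidates[sort(best$sel)]
  fit_terms(d, terms, "subset", p_crit, empty = is.null(best))
}

#' Domain-specific models
#'
#' For each of the ten domains, reduces the stage-1 survivors of that domain
#' to a domain-specific multivariable model (default: backwards stepwise).
#' Emits a per-domain summary (total variables, stage-1 selected, model df
#' and R-squared) and a per-variable table comparing the unadjusted slope
#' with the within-domain adjusted slope.
#'
#' @param em a completed standardized \code{\link{exposome_matrix}}.
#' @param outcome numeric outcome vector.
#' @param screen_results \code{screen_result} with \code{passes_fdr} flags
#'   (see \code{\link{apply_prior_hypotheses}}).
#' @param method stepwise method for the domain stage (default backwards).
#' @param p_crit significance criterion (typically the stage-1 FDR nominal
#'   critical value).
#' @return list with \code{fits} (named by domain), \code{summary}
#'   (Table-1-style counts) and \code{table} (Table-2-style coefficients).
#' @export
domain_models <- function(em, outcome, screen_results, method = "backwards",
                          p_crit) {
  stopifnot("passes_fdr" %in% names(screen_results))
  survivors <- screen_results$name[screen_results$passes_fdr]
  doms <- DOMAIN_LABELS[DOMAIN_LABELS %in% unique(screen_results$domain)]
  fits <- list()
  summ <- NULL
  tab2 <- NULL
  for (dm in doms) {
    in_dom <- screen_results$name[screen_results$domain == dm]
    cands <- intersect(intersect(in_dom, survivors), colnames(em$data))
    sf <- stepwise_fit(em, outcome, cands, method = method, p_crit = p_crit)
    fits[[dm]] <- sf$fit
    summ <- rbind(summ, data.frame(
      domain = dm, n_total = length(in_dom), n_selected = length(cands),
      df = length(sf$fit$terms), r_squared = sf$fit$r_squared))
    if (length(sf$fit$terms)) {
      i <- match(sf$fit$terms, screen_results$name)
      j <- match(sf$fit$terms, sf$fit$table$term)
      tab2 <- rbind(tab2, data.frame(
        domain = dm, term = sf$fit$terms,
        B_unadjusted = screen_results$B[i],
        B_adjusted = sf$fit$table$B[j],
        p_adjusted = sf$fit$table$p[j],
        partial_r = sf$fit$table$partial_r[j],
        rank_unadjusted = screen_results$rank[i]))
    }
  }
  if (is.null(tab2)) tab2 <- data.frame(
    domain = character(0), term = character(0), B_unadjusted = numeric(0),
    B_adjusted = numeric(0), p_adjusted = numeric(0),
    partial_r = numeric(0), rank_unadjusted = integer(0))
  list(fits = fits, summary = summ, table = tab2)
}

#' Combined final model
#'
#' Pools the variables retained in any domain model and reduces them with
#' the requested stepwise method (default: subset search). When screening
#' results are supplied, a contribution decomposition by unadjusted-rank
#' tier is attached: the incremental R-squared of the top-five unadjusted
#' ranks, the next five, and the remainder.
#'
#' @param em a completed standardized \code{\link{exposome_matrix}}.
#' @param outcome numeric outcome vector.
#' @param domain_fits result of \code{\link{domain_models}}.
#' @param method stepwise method (default \code{"subset"}).
#' @param p_crit significance criterion.
#' @param screen_results optional \code{screen_result} for the tier
#'   decomposition.
#' @param ... passed to \code{\link{stepwise_fit}}.
#' @return a \code{model_fit} with optional \code{$tiers} decomposition.
#' @export
final_model <- function(em, outcome, domain_fits, method = "subset",
                        p_crit, screen_results = NULL, ...) {
  pool <- unique(unlist(lapply(domain_fits$fits, function(f) f$terms)))
  pool <- intersect(em$codebook$name, pool)   # codebook order
  sf <- stepwise_fit(em, outcome, pool, method = method, p_crit = p_crit,
                     ...)
  fit <- sf$fit
  fit$candidate_pool <- pool
  if (!is.null(screen_results) && length(fit$terms)) {
    rk <- screen_results$rank[match(fit$terms, screen_results$name)]
    ordered <- fit$terms[order(rk)]
    cuts <- list(top5 = seq_len(min(5, length(ordered))))
    if (length(ordered) > 5)
      cuts$next5 <- seq(6, min(10, length(ordered)))
    if (length(ordered) > 10)
      cuts$rest <- seq(11, length(ordered))
    d <- prepare_selection(em, outcome, fit$terms)
    acc <- character(0); r2_prev <- 0; rows <- NULL
    for (nm in names(cuts)) {
      acc <- c(acc, ordered[cuts[[nm]]])
      r2 <- fit_terms(d, acc, "tier", p_crit)$r_squared
      rows <- rbind(rows, data.frame(
        tier = nm, n_variables = length(cuts[[nm]]),
        rank_range = paste(range(rk[match(ordered[cuts[[nm]]],
                                          fit$terms)]), collapse = "-"),
        incremental_r2 = r2 - r2_prev,
        share_of_total = (r2 - r2_prev) / fit$r_squared))
      r2_prev <- r2
    }
    fit$tiers <- rows
  }
  fit
}

#' Partial correlation of a fitted variable
#'
#' The correlation between a model variable and the outcome after removing
#' the linear effect of the other model terms:
#' sign(B) * sqrt(t^2 / (t^2 + df)) for the variable's t statistic in the
#' joint fit. This is the within-model ranking statistic (nearly equivalent
#' to ranking by standardized effect size).
#'
#' @param fit a \code{model_fit}.
#' @param variable a variable name in the fit.
#' @return partial correlation in [-1, 1].
#' @export
partial_correlation <- function(fit, variable) {
  stopifnot(inherits(fit, "model_fit"))
  if (fit$df <= 0) stop("no residual degrees of freedom")
  i <- match(variable, fit$table$term)
  if (is.na(i)) stop("variable not in fit: ", variable)
  tt <- fit$table$t[i]
  if (tt == 0) return(0)
  sign(tt) * sqrt(tt^2 / (tt^2 + fit$df))
}

#' Attenuation of effect sizes under adjustment
#'
#' For variables present both in the unadjusted scan and an adjusted model,
#' attenuation = 100 (1 - B_adj / B_unadj) percent. Variables whose adjusted
#' coefficient changed sign (or grew) are reported separately and excluded
#' from the mean and range.
#'
#' @param screen_results unadjusted \code{screen_result}.
#' @param adjusted a \code{model_fit}, or the \code{table} element of
#'   \code{\link{domain_models}} (columns \code{term}, \code{B_adjusted}).
#' @return list with per-variable \code{table}, \code{mean_attenuation},
#'   \code{range_attenuation} and \code{sign_flips}.
#' @export
attenuation_summary <- function(screen_results, adjusted) {
  if (inherits(adjusted, "model_fit")) {
    adj <- data.frame(term = adjusted$table$term, B_adjusted =
                        adjusted$table$B, stringsAsFactors = FALSE)
    adj <- adj[adj$term %in% screen_results$name, , drop = FALSE]
  } else {
    adj <- adjusted[, c("term", "B_adjusted")]
  }
  i <- match(adj$term, screen_results$name)
  if (anyNA(i)) stop("adjusted variables missing from screen results: ",
                     paste(adj$term[is.na(i)], collapse = ", "))
  bu <- screen_results$B[i]
  if (any(bu == 0)) stop("unadjusted coefficient of zero; ",
                         "attenuation undefined")
  att <- 100 * (1 - adj$B_adjusted / bu)
  flip <- sign(adj$B_adjusted) * sign(bu) < 0
  tab <- data.frame(term = adj$term, B_unadjusted = bu,
                    B_adjusted = adj$B_adjusted, attenuation_pct = att,
                    sign_flip = flip, stringsAsFactors = FALSE)
  ok <- !flip & att >= 0
  list(table = tab,
       mean_attenuation = if (any(ok)) mean(att[ok]) else NA_real_,
       range_attenuation = if (any(ok)) range(att[ok]) else
         c(NA_real_, NA_real_),
       sign_flips = tab$term[flip])
}
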