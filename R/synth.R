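# Synthetic exposome generator. Emulates the structure the scan assumes: a
# large questionnaire exposome (thousands of mixed binary/ordinal/continuous
# variables in 10 thematically correlated domains), a right-bounded
# left-skewed continuous outcome, planted standardized linear effects of the
# magnitude seen in real final models (~0.4-0.8 outcome points per exposure
# SD), MCAR or MAR missingness, and a small fraction of subjects without a
# partner whose partner-reported variables are wholly missing.

#' Default planted-effect layout
#'
#' Two planted variables per domain (the first two columns of each domain
#' block), magnitudes evenly spaced over \code{beta_range}, with the sign
#' alternating by domain: both effects inside a domain share a sign, and
#' adjacent domains have opposite signs. Real exposome scans find both
#' beneficial and adverse exposures, and a world where all effects share one
#' sign would make every cross-correlated null variable spuriously
#' associated.
#'
#' @param n_variables,n_domains layout of the exposome.
#' @param n_effects number of planted effects (default 20).
#' @param beta_range magnitude range in outcome points per exposure SD.
#' @return data.frame with columns \code{id}, \code{beta}.
#' @export
default_planted_effects <- function(n_variables = 600, n_domains = 10,
                                    n_effects = 20,
                                    beta_range = c(0.4, 0.8)) {
  per_dom <- n_variables %/% n_domains
  k <- ceiling(n_effects / n_domains)
  ids <- unlist(lapply(seq_len(n_domains) - 1L,
                       function(d) d * per_dom + seq_len(k)))[seq_len(n_effects)]
  dom <- (ids - 1L) %/% per_dom + 1L
  beta <- seq(beta_range[1], beta_range[2], length.out = n_effects) *
    ifelse(dom %% 2 == 1, 1, -1)
  data.frame(id = as.integer(ids), beta = beta)
}

#' Specification of a synthetic exposome world
#'
#' Collects every parameter of the generator. Defaults describe the
#' desk-scale stand-in for a large birth-cohort questionnaire exposome:
#' 7,600 analysis subjects (the scale of an observed-outcome sample),
#' 600 variables in 10 domains, a latent block-exchangeable correlation
#' (0.3 within domains, 0.1 across), a mixed marginal palette, 20 planted
#' effects of 0.4-0.8 outcome points per exposure SD, a left-skewed outcome
#' bounded on 126-232 with noise SD 7 (so the planted effects explain roughly
#' 13\% of outcome variance), 16\% MAR missingness, and 2.0\% of subjects
#' without a partner.
#'
#' @param n_subjects,n_variables,n_domains sample and exposome size.
#' @param within_domain_corr,cross_domain_corr latent correlations; must give
#'   a positive-definite block matrix (requires
#'   \code{0 <= cross < within < 1}, or both zero).
#' @param type_mix named proportions for binary/ordinal/continuous marginals.
#' @param planted_effects data.frame (\code{id}, \code{beta}) of linear
#'   effects on the standardized latent variables.
#' @param planted_interactions data.frame (\code{id1}, \code{id2},
#'   \code{gamma}) of product-term effects, or \code{NULL}.
#' @param mediator_spec optional list(\code{loadings} = named numeric on
#'   planted variable ids, \code{effect}, \code{noise_sd}): a mediator M is
#'   built from the loaded latents plus noise and enters the outcome with
#'   coefficient \code{effect}.
#' @param outcome_baseline,outcome_noise_sd,outcome_skew,outcome_bounds
#'   outcome construction: baseline mean, residual SD in outcome points,
#'   sinh-arcsinh skewness (negative = left skew), truncation bounds.
#' @param missing_rate,missing_mechanism proportion of exposure cells set
#'   missing and the mechanism (\code{"MCAR"} or \code{"MAR"}; MAR is driven
#'   by two fully observed continuous anchor variables per domain).
#' @param partnerless_rate fraction of subjects with no partner.
#' @param partner_fraction fraction of variables that are partner-reported.
#' @param seed integer RNG seed.
#' @return object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_subjects = 7600, n_variables = 600,
                           n_domains = 10,
                           within_domain_corr = 0.3, cross_domain_corr = 0.1,
                           type_mix = c(binary = 0.3, ordinal = 0.4,
                                        continuous = 0.3),
                           planted_effects = default_planted_effects(
                             n_variables, n_domains),
                           planted_interactions = NULL,
                           mediator_spec = NULL,
                           outcome_baseline = 205, outcome_noise_sd = 7,
                           outcome_skew = -0.5,
                           outcome_bounds = c(126, 232),
                           missing_rate = 0.16,
                           missing_mechanism = c("MAR", "MCAR"),
                           partnerless_rate = 0.020,
                           partner_fraction = 0.15,
                           seed = 1L) {
  missing_mechanism <- match.arg(missing_mechanism)
  spec <- list(n_subjects = n_subjects, n_variables = n_variables,
               n_domains = n_domains,
               within_domain_corr = within_domain_corr,
               cross_domain_corr = cross_domain_corr,
               type_mix = type_mix / sum(type_mix),
               planted_effects = planted_effects,
               planted_interactions = planted_interactions,
               mediator_spec = mediator_spec,
               outcome_baseline = outcome_baseline,
               outcome_noise_sd = outcome_noise_sd,
               outcome_skew = outcome_skew,
               outcome_bounds = outcome_bounds,
               missing_rate = missing_rate,
               missing_mechanism = missing_mechanism,
               partnerless_rate = partnerless_rate,
               partner_fraction = partner_fraction,
               seed = as.integer(seed))
  class(spec) <- "synthetic_spec"
  validate_synthetic_spec(spec)
  spec
}

validate_synthetic_spec <- function(spec) {
  rw <- spec$within_domain_corr; rc <- spec$cross_domain_corr
  if (rw < 0 || rw >= 1 || rc < 0 || rc > rw)
    stop("correlation request is not positive definite: need ",
         "0 <= cross_domain_corr <= within_domain_corr < 1")
  pe <- spec$planted_effects
  if (!is.null(pe) && nrow(pe)) {
    if (any(pe$id < 1 | pe$id > spec$n_variables))
      stop("planted effect ids must lie in 1..n_variables")
    if (anyDuplicated(pe$id))
      stop("a variable appears twice in planted_effects")
  }
  if (spec$missing_rate < 0 || spec$missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (spec$outcome_bounds[1] >= spec$outcome_bounds[2])
    stop("outcome_bounds must be increasing")
  invisible(spec)
}

# moments of sinh(asinh(Z) + eps) for a standard normal Z, so skewed noise
# can be rescaled to exact mean 0 / SD 1 analytically (deterministically)
shash_moments <- function(eps) {
  e_sqrt <- stats::integrate(function(z) sqrt(1 + z^2) * stats::dnorm(z),
                             -Inf, Inf)$value
  m1 <- sinh(eps) * e_sqrt
  m2 <- cosh(eps)^2 + 2 * sinh(eps)^2
  c(mean = m1, sd = sqrt(m2 - m1^2))
}

# skewed noise: sinh-arcsinh transform of Gaussian noise, standardized
rshash <- function(n, skew) {
  z <- stats::rnorm(n)
  if (skew == 0) return(z)
  x <- sinh(asinh(z) + skew)
  mo <- shash_moments(skew)
  (x - mo["mean"]) / mo["sd"]
}

#' Generate a synthetic exposome dataset
#'
#' Draws latent Gaussian variables with the requested block-exchangeable
#' correlation, discretizes them per variable type through Gaussian-copula
#' quantile thresholds (one cutpoint for binary, 3-5 equal-probability
#' cutpoints for ordinal, identity for continuous), builds the outcome as a
#' linear combination of planted effects on the standardized latents plus
#' optional interaction products, an optional mediator path and skewed noise
#' truncated to the feasible bounds, then applies missingness and the
#' partnerless-subject gap.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return list with \code{matrix} (an \code{\link{exposome_matrix}}),
#'   \code{outcome}, \code{truth} (a \code{truth_record}), \code{latent}
#'   (the pre-discretization standardized latents, for calibration checks)
#'   and \code{mediator} (or \code{NULL}).
#' @export
generate_exposome <- function(spec) {
  validate_synthetic_spec(spec)
  set.seed(spec$seed)
  n <- spec$n_subjects; m <- spec$n_variables; K <- spec$n_domains
  rw <- spec$within_domain_corr; rc <- spec$cross_domain_corr
  per_dom <- m %/% K
  domain_of <- pmin((seq_len(m) - 1L) %/% per_dom + 1L, K)

  # latent draws: shared factor + domain factor + unique part
  zc <- stats::rnorm(n)
  zd <- matrix(stats::rnorm(n * K), n, K)
  Z <- sqrt(rc) * zc + sqrt(rw - rc) * zd[, domain_of] +
    matrix(stats::rnorm(n * m), n, m) * sqrt(1 - rw)

  # marginal types; the last two variables of each domain are continuous
  # "anchor" variables, fully observed, that drive MAR missingness
  counts <- round(spec$type_mix * m)
  counts["continuous"] <- m - counts["binary"] - counts["ordinal"]
  types <- rep(names(counts), counts)[seq_len(m)]
  types <- sample(types)
  anchors <- as.vector(vapply(seq_len(K), function(d) {
    i <- which(domain_of == d); utils::tail(i, 2)
  }, integer(2)))
  types[anchors] <- "continuous"

  pe <- spec$planted_effects
  planted_ids <- if (is.null(pe)) integer(0) else pe$id
  # planted effects act on the standardized latents; keeping the planted
  # columns continuous makes the observed-scale effect equal the planted
  # magnitude (discretized marginals would attenuate it by the
  # latent-observed correlation)
  types[planted_ids] <- "continuous"

  vnames <- sprintf("v%04d", seq_len(m))
  cuts <- vector("list", m)
  X <- Z
  for (j in seq_len(m)) {
    if (types[j] == "binary") {
      prev <- stats::runif(1, 0.15, 0.85)
      cuts[[j]] <- stats::qnorm(1 - prev)
      X[, j] <- as.numeric(Z[, j] > cuts[[j]])
    } else if (types[j] == "ordinal") {
      ncut <- sample(3:5, 1)
      cuts[[j]] <- stats::qnorm(seq_len(ncut) / (ncut + 1))
      X[, j] <- findInterval(Z[, j], cuts[[j]])
    }
  }
  if (length(planted_ids)) {
    degen <- vapply(planted_ids,
                    function(j) length(unique(X[, j])) < 2, logical(1))
    if (any(degen))
      stop("planted effect on a degenerate (all-constant) variable: ",
           paste(vnames[planted_ids[degen]], collapse = ", "))
  }

  # outcome on the latent (exactly standardized) scale
  eta <- rep(spec$outcome_baseline, n)
  if (length(planted_ids))
    eta <- eta + Z[, planted_ids, drop = FALSE] %*% pe$beta
  pi_ <- spec$planted_interactions
  if (!is.null(pi_) && nrow(pi_))
    for (i in seq_len(nrow(pi_)))
      eta <- eta + pi_$gamma[i] * Z[, pi_$id1[i]] * Z[, pi_$id2[i]]
  mediator <- NULL
  ms <- spec$mediator_spec
  if (!is.null(ms)) {
    lo <- ms$loadings
    mediator <- as.vector(Z[, as.integer(names(lo)), drop = FALSE] %*% lo) +
      stats::rnorm(n, sd = ms$noise_sd)
    eta <- eta + ms$effect * mediator
  }
  y <- as.vector(eta) + spec$outcome_noise_sd * rshash(n, spec$outcome_skew)
  y <- pmin(pmax(y, spec$outcome_bounds[1]), spec$outcome_bounds[2])

  # reporter assignment and partnerless gap
  reporter <- rep("mother", m)
  n_partner_vars <- round(spec$partner_fraction * m)
  if (n_partner_vars > 0) {
    pool <- setdiff(seq_len(m), anchors)
    reporter[sample(pool, min(n_partner_vars, length(pool)))] <- "partner"
  }
  partner_status <- integer(n)
  n_pl <- round(spec$partnerless_rate * n)
  if (n_pl > 0) partner_status[sample(n, n_pl)] <- 1L

  # missingness on exposure cells (anchors stay fully observed under MAR)
  if (spec$missing_rate > 0) {
    if (spec$missing_mechanism == "MCAR") {
      miss <- matrix(stats::runif(n * m) < spec$missing_rate, n, m)
    } else {
      miss <- matrix(FALSE, n, m)
      for (d in seq_len(K)) {
        a <- anchors[c(2 * d - 1, 2 * d)]
        s <- 0.5 * Z[, a[1]] + 0.5 * Z[, a[2]]
        a0 <- stats::uniroot(function(a0) mean(stats::plogis(a0 + s)) -
                               spec$missing_rate, c(-30, 30))$root
        p <- stats::plogis(a0 + s)
        idx <- setdiff(which(domain_of == d), a)
        miss[, idx] <- stats::runif(n * length(idx)) <
          matrix(p, n, length(idx))
      }
    }
    X[miss] <- NA
  }
  if (n_pl > 0) X[partner_status == 1L, reporter == "partner"] <- NA

  colnames(X) <- vnames
  ranges <- t(vapply(seq_len(m), function(j) {
    switch(types[j],
           binary = c(0, 1),
           ordinal = c(0, length(cuts[[j]])),
           continuous = c(-Inf, Inf))
  }, numeric(2)))
  cb <- exposure_codebook(vnames, DOMAIN_LABELS[domain_of],
                          reporter = reporter, var_type = types,
                          direction = 1L, range_low = ranges[, 1],
                          range_high = ranges[, 2])
  em <- exposome_matrix(X, cb, partner_status = partner_status)

  truth <- structure(list(
    spec = spec,
    planted_effects = if (length(planted_ids))
      data.frame(id = pe$id, name = vnames[pe$id], beta = pe$beta)
    else data.frame(id = integer(0), name = character(0), beta = numeric(0)),
    planted_interactions = pi_,
    mediator_spec = ms,
    missing_mechanism = spec$missing_mechanism,
    missing_rate = spec$missing_rate,
    anchor_ids = anchors,
    var_type = stats::setNames(types, vnames),
    seed = spec$seed), class = "truth_record")

  colnames(Z) <- vnames
  list(matrix = em, outcome = y, truth = truth, latent = Z,
       mediator = mediator)
}

#' Regenerate a dataset from its truth record
#'
#' A truth record embeds the full generator spec (including the seed), so the
#' dataset can be rebuilt bit-identically by the same generator version.
#'
#' @param truth a \code{truth_record}.
#' @return as \code{\link{generate_exposome}}.
#' @export
regenerate_exposome <- function(truth) {
  stopifnot(inherits(truth, "truth_record"))
  generate_exposome(truth$spec)
}

#' Null p-value fixture
#'
#' @param m number of draws (must be >= 1).
#' @param seed RNG seed.
#' @return \code{m} i.i.d. Uniform(0,1) p-values.
#' @export
generate_null_pvalue_set <- function(m, seed = 1L) {
  if (m < 1) stop("m must be >= 1")
  set.seed(seed)
  stats::runif(m)
}
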