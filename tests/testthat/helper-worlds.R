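# Shared fixture builders: all fixtures are generated in code.

# wrap a plain numeric matrix as an exposome_matrix with a minimal codebook
as_em <- function(X, reporter = "mother", var_type = "continuous",
                  partner_status = NULL, domain = NULL) {
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%02d", seq_len(ncol(X)))
  if (is.null(domain))
    domain <- rep_len(DOMAIN_LABELS, ncol(X))
  cb <- exposure_codebook(colnames(X), domain, reporter = reporter,
                          var_type = var_type)
  exposome_matrix(X, cb, partner_status = partner_status)
}

# independent standard-normal design with outcome y = X beta + noise
lin_world <- function(n, betas, noise_sd = 1, seed = 1) {
  set.seed(seed)
  p <- length(betas)
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X %*% betas) + rnorm(n, sd = noise_sd)
  list(em = standardize(as_em(X)), y = y, X = X)
}

# brute-force BH step-up oracle: check every index i explicitly
bh_oracle <- function(p, q) {
  m <- length(p)
  s <- sort(p)
  istar <- 0
  for (i in seq_len(m)) if (s[i] <= i * q / m) istar <- i
  if (istar == 0) rep(FALSE, m) else p <= s[istar]
}

# exhaustive best-subset oracle using lm(): max R^2 among subsets whose
# members are all significant at p_crit in the joint fit
subset_oracle <- function(X, y, p_crit) {
  k <- ncol(X)
  best <- list(r2 = -Inf, sel = integer(0))
  for (mask in seq_len(2^k - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
    df <- data.frame(y = y, X[, sel, drop = FALSE])
    f <- stats::lm(y ~ ., data = df)
    sm <- summary(f)
    pv <- stats::coef(sm)[-1, 4]
    if (any(is.na(stats::coef(f)))) next
    if (all(pv <= p_crit) && sm$r.squared > best$r2 + 1e-10)
      best <- list(r2 = sm$r.squared, sel = sel)
  }
  best
}
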