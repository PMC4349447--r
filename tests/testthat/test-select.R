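# Stepwise and best-subset selection, partial correlation, attenuation.

test_that("a single overwhelming candidate is selected by all methods", {
  w <- lin_world(400, c(1.5, 0, 0), seed = 11)
  for (m in c("forwards", "backwards", "subset")) {
    sf <- stepwise_fit(w$em, w$y, colnames(w$em$data), method = m,
                       p_crit = 1e-4)
    expect_identical(sf$fit$terms, "x01")
    expect_identical(sf$fit$method, if (m == "subset") "subset" else m)
  }
})

test_that("duplicate predictors: exactly one survives, tie is recorded", {
  set.seed(12)
  n <- 300
  x <- rnorm(n)
  X <- cbind(a = x, b = x, c = rnorm(n))
  y <- 2 * x + rnorm(n)
  em <- standardize(as_em(X))
  sf <- stepwise_fit(em, y, c("a", "b", "c"), method = "forwards",
                     p_crit = 1e-3)
  expect_identical(sf$fit$terms, "a")       # candidate order breaks the tie
  expect_true(any(sf$trace$tie))
  sb <- stepwise_fit(em, y, c("a", "b", "c"), method = "subset",
                     p_crit = 1e-3)
  expect_length(intersect(sb$fit$terms, c("a", "b")), 1)
  bk <- stepwise_fit(em, y, c("a", "b", "c"), method = "backwards",
                     p_crit = 1e-3)
  expect_length(intersect(bk$fit$terms, c("a", "b")), 1)
  expect_true("remove_aliased" %in% bk$trace$action)
})

test_that("every returned model satisfies the criterion post-condition", {
  set.seed(13)
  for (rep in 1:8) {
    n <- 250
    X <- matrix(rnorm(n * 8), n, 8,
                dimnames = list(NULL, sprintf("x%02d", 1:8)))
    X[, 2] <- X[, 1] * 0.8 + rnorm(n, sd = 0.6)
    y <- X[, 1] - 0.6 * X[, 3] + rnorm(n)
    em <- standardize(as_em(X))
    for (m in c("forwards", "backwards", "subset")) {
      fit <- stepwise_fit(em, y, colnames(X), method = m,
                          p_crit = 0.01)$fit
      if (length(fit$terms)) {
        pv <- fit$table$p[match(fit$terms, fit$table$term)]
        expect_true(all(pv <= 0.01))
      }
    }
  }
})

test_that("forwards trace replays to the final set with monotone R^2", {
  w <- lin_world(500, c(0.8, -0.5, 0.3, 0, 0, 0), seed = 14)
  sf <- stepwise_fit(w$em, w$y, colnames(w$em$data), method = "forwards",
                     p_crit = 0.001)
  added <- sf$trace$variable[sf$trace$action == "add"]
  expect_identical(sort(added), sort(sf$fit$terms))
  r2 <- vapply(seq_along(added), function(k)
    refit_model(w$em, w$y, added[seq_len(k)])$r_squared, numeric(1))
  expect_true(all(diff(r2) > -1e-12))
  expect_equal(r2[length(r2)], sf$fit$r_squared, tolerance = 1e-12)
})

test_that("best_subset_search equals the lm() enumeration oracle", {
  set.seed(15)
  for (rep in 1:10) {
    n <- 120
    k <- sample(4:8, 1)
    X <- matrix(rnorm(n * k), n, k,
                dimnames = list(NULL, sprintf("x%02d", 1:k)))
    X[, 2] <- X[, 1] + rnorm(n, sd = 0.5)   # correlated pair
    beta <- c(0.7, 0, runif(k - 2, -0.4, 0.4))
    y <- drop(X %*% beta) + rnorm(n)
    em <- standardize(as_em(X))
    p_crit <- sample(c(0.01, 0.05), 1)
    # scaling does not change subset selection, p-values or R^2
    fit <- best_subset_search(em, y, colnames(X), p_crit = p_crit)
    oracle <- subset_oracle(X, y, p_crit)
    expect_identical(sort(match(fit$terms, colnames(X))),
                     sort(oracle$sel))
    if (length(oracle$sel))
      expect_equal(fit$r_squared, oracle$r2, tolerance = 1e-10)
  }
})

test_that("branch-and-bound regime equals the exhaustive regime", {
  set.seed(16)
  for (rep in 1:10) {
    n <- 150
    k <- 10
    X <- matrix(rnorm(n * k), n, k,
                dimnames = list(NULL, sprintf("x%02d", 1:k)))
    X[, 3] <- 0.6 * X[, 1] - 0.5 * X[, 2] + rnorm(n, sd = 0.7)
    y <- 0.6 * X[, 1] + 0.4 * X[, 4] + rnorm(n)
    em <- standardize(as_em(X))
    for (p_crit in c(0.01, 0.2)) {
      ex <- best_subset_search(em, y, colnames(X), p_crit = p_crit,
                               max_exhaustive = 15)
      bb <- best_subset_search(em, y, colnames(X), p_crit = p_crit,
                               max_exhaustive = 0)
      expect_identical(bb$terms, ex$terms)
      expect_equal(bb$r_squared, ex$r_squared, tolerance = 1e-12)
    }
  }
})

test_that("suppressor pair: subset finds what forwards cannot", {
  # x1, x2 jointly predictive but marginally null: y = x1 - x2 with
  # cor(x1, x2) high, so each marginal slope is tiny
  set.seed(17)
  n <- 600
  x1 <- rnorm(n)
  x2 <- 0.95 * x1 + sqrt(1 - 0.95^2) * rnorm(n)
  y <- 2.5 * (x1 - x2) + rnorm(n)
  X <- cbind(x1 = x1, x2 = x2, noise = rnorm(n))
  em <- standardize(as_em(X))
  p_crit <- 1e-4
  fw <- stepwise_fit(em, y, colnames(X), "forwards", p_crit)$fit
  sb <- stepwise_fit(em, y, colnames(X), "subset", p_crit)$fit
  expect_setequal(sb$terms, c("x1", "x2"))
  expect_false(all(c("x1", "x2") %in% fw$terms))
  expect_gte(sb$r_squared, fw$r_squared)
})

test_that("empty admissible set yields a flagged intercept-only fit", {
  w <- lin_world(200, c(0, 0, 0), seed = 18)
  fit <- best_subset_search(w$em, w$y, colnames(w$em$data),
                            p_crit = 1e-8)
  expect_true(fit$empty)
  expect_length(fit$terms, 0)
  expect_equal(fit$r_squared, 0, tolerance = 1e-12)
})

test_that("domain models cover all domains and nest inside the union", {
  set.seed(19)
  n <- 600
  X <- matrix(rnorm(n * 20), n, 20,
              dimnames = list(NULL, sprintf("x%02d", 1:20)))
  dom <- rep(DOMAIN_LABELS[1:4], each = 5)
  y <- 1.2 * X[, 1] - 1.0 * X[, 6] + rnorm(n)
  em <- standardize(as_em(X, domain = dom))
  scan <- apply_prior_hypotheses(univariable_scan(em, y), q = 0.001)
  dm <- domain_models(em, y, scan, p_crit = 0.001)
  expect_setequal(dm$summary$domain, DOMAIN_LABELS[1:4])
  # truth confined to domains 1 and 2: others give empty fits
  expect_gt(length(dm$fits[[DOMAIN_LABELS[1]]]$terms), 0)
  expect_gt(length(dm$fits[[DOMAIN_LABELS[2]]]$terms), 0)
  # per-domain R^2 never exceeds the union fit's R^2 (OLS nesting)
  union_fit <- refit_model(em, y, unique(unlist(
    lapply(dm$fits, function(f) f$terms))))
  for (f in dm$fits)
    expect_lte(f$r_squared, union_fit$r_squared + 1e-12)
  ff <- final_model(em, y, dm, method = "subset", p_crit = 0.001,
                    screen_results = scan)
  expect_setequal(ff$terms, c("x01", "x06"))
  expect_true(!is.null(ff$tiers))
})

test_that("partial correlation matches its algebraic identities", {
  set.seed(20)
  n <- 200
  X <- matrix(rnorm(n * 3), n, 3)
  y <- 0.5 * X[, 1] - 0.3 * X[, 2] + rnorm(n)
  em <- standardize(as_em(X))
  # single-predictor model: partial r equals marginal Pearson r
  f1 <- refit_model(em, y, "x01")
  expect_equal(partial_correlation(f1, "x01"), cor(X[, 1], y),
               tolerance = 1e-10)
  # 3-predictor fit: equals the residual-on-residual correlation oracle
  f3 <- refit_model(em, y, c("x01", "x02", "x03"))
  rx <- resid(lm(X[, 2] ~ X[, 1] + X[, 3]))
  ry <- resid(lm(y ~ X[, 1] + X[, 3]))
  expect_equal(partial_correlation(f3, "x02"), cor(rx, ry),
               tolerance = 1e-10)
  expect_error(partial_correlation(f3, "zz"), "not in fit")
})

test_that("attenuation arithmetic and sign-flip handling", {
  scan <- structure(data.frame(name = c("a", "b", "c", "d"),
                               domain = "health",
                               B = c(-1.0, 2.0, 1.0, 1.0),
                               se = 0.1, p = 1e-6, r2 = 0.1, n = 100,
                               rank = 1:4),
                    class = c("screen_result", "data.frame"))
  adj <- data.frame(term = c("a", "b", "c", "d"),
                    B_adjusted = c(-0.59, 2.0, 0, -0.5))
  att <- attenuation_summary(scan, adj)
  expect_equal(att$table$attenuation_pct, c(41, 0, 100, 150))
  expect_identical(att$sign_flips, "d")
  expect_equal(att$mean_attenuation, mean(c(41, 0, 100)))
  expect_equal(att$range_attenuation, c(0, 100))
  scan$B[1] <- 0
  expect_error(attenuation_summary(scan, adj), "zero")
})
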