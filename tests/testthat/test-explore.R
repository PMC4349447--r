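# Post-model probes: interactions, quadratics, mediation, prevalence shift.

probe_world <- function(n = 1500, seed = 30, gamma = 0, quad = 0) {
  set.seed(seed)
  X <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(NULL, paste0("v", 1:4)))
  y <- 0.8 * X[, 1] - 0.6 * X[, 2] + 0.5 * X[, 3] +
    gamma * X[, 1] * X[, 2] + quad * X[, 3]^2 + rnorm(n)
  em <- standardize(as_em(X))
  fit <- refit_model(em, y, c("v1", "v2", "v3"))
  list(em = em, y = y, fit = fit)
}

test_that("interaction scan tests every pair and finds a planted product", {
  w <- probe_world(gamma = 0.4, seed = 31)
  sc <- interaction_scan(w$fit, w$em, w$y, p_crit = 0.001)
  expect_equal(nrow(sc), choose(3, 2))
  hit <- sc[sc$var1 == "v1" & sc$var2 == "v2", ]
  expect_true(hit$significant)
  expect_equal(hit$gamma, 0.4, tolerance = 0.15)
  grids <- attr(sc, "grids")
  expect_true("v1:v2" %in% names(grids))
  expect_equal(dim(grids[["v1:v2"]]$mean), c(5, 5))   # quintile grid
  # k = 2 model tests exactly one pair
  f2 <- refit_model(w$em, w$y, c("v1", "v2"))
  expect_equal(nrow(interaction_scan(f2, w$em, w$y)), 1)
  # a 19-variable model would test 171 pairs, as k(k-1)/2 requires
  expect_equal(choose(19, 2), 171)
})

test_that("binary-with-itself products are skipped, not mis-tested", {
  set.seed(32)
  n <- 400
  xb <- rbinom(n, 1, 0.5)
  X <- cbind(b1 = xb, b2 = xb, c1 = rnorm(n))  # b1*b2 == b1 (collinear)
  y <- xb + X[, "c1"] + rnorm(n)
  em <- standardize(as_em(X))
  fit <- refit_model(em, y, c("b1", "b2", "c1"))
  sc <- interaction_scan(fit, em, y)
  expect_true(sc$skipped[sc$var1 == "b1" & sc$var2 == "b2"])
})

test_that("greedy reduction keeps the planted pair and drops its echoes", {
  # one planted interaction induces correlated apparent interactions via a
  # variable correlated with a true moderator
  set.seed(33)
  n <- 4000
  x1 <- rnorm(n); x2 <- rnorm(n)
  x3 <- 0.8 * x2 + sqrt(1 - 0.64) * rnorm(n)
  X <- cbind(a = x1, b = x2, c = x3)
  y <- 0.5 * x1 + 0.4 * x2 + 0.3 * x3 + 0.45 * x1 * x2 + rnorm(n)
  em <- standardize(as_em(X))
  fit <- refit_model(em, y, c("a", "b", "c"))
  sc <- interaction_scan(fit, em, y, p_crit = 0.001)
  expect_true(sc$significant[sc$var1 == "a" & sc$var2 == "b"])
  red <- reduce_interactions(sc, em, y, fit)
  expect_true(any(red$retained$var1 == "a" & red$retained$var2 == "b"))
  # reduction output is a subset of its input
  expect_lte(nrow(red$retained), sum(sc$significant))
  # empty input: empty output
  sc0 <- sc; sc0$significant <- FALSE
  red0 <- reduce_interactions(sc0, em, y, fit)
  expect_equal(nrow(red0$retained), 0)
})

test_that("quadratic tests flag curvature and refuse binaries", {
  w <- probe_world(quad = 0.3, seed = 34)
  qt <- quadratic_tests(w$fit, w$em, w$y, p_crit = 0.001)
  expect_true(all(qt$testable))
  expect_true(qt$significant[qt$term == "v3"])
  expect_false(qt$significant[qt$term == "v1"])
  # binary variable: untestable
  set.seed(35)
  n <- 300
  X <- cbind(b = rbinom(n, 1, 0.4), c = rnorm(n))
  y <- X[, "b"] + X[, "c"] + rnorm(n)
  em <- standardize(as_em(X))
  fit <- refit_model(em, y, c("b", "c"))
  qt2 <- quadratic_tests(fit, em, y)
  expect_false(qt2$testable[qt2$term == "b"])
  expect_true(qt2$testable[qt2$term == "c"])
})

test_that("mediation attenuation matches path arithmetic", {
  set.seed(36)
  n <- 20000
  x <- rnorm(n)
  # full mediation: x -> m -> y, no direct path
  m_full <- 0.8 * x + rnorm(n, sd = 0.6)
  y_full <- 1.0 * m_full + rnorm(n)
  X <- cbind(x = x, z = rnorm(n))
  em <- standardize(as_em(X))
  fit <- refit_model(em, y_full, "x")
  md <- mediation_analysis(fit, em, y_full, cbind(iq = m_full))
  expect_equal(md$table$attenuation_pct[1], 100, tolerance = 5)
  expect_true(md$table$no_direct_effect[1])
  expect_equal(md$share_mediated_pct, 100, tolerance = 6)
  # half mediation: direct = indirect (a*b = c)
  m_half <- 0.8 * x + rnorm(n, sd = 0.6)
  y_half <- 0.4 * x + 0.5 * m_half + rnorm(n)   # indirect 0.8*0.5 = direct
  fit_h <- refit_model(em, y_half, "x")
  md_h <- mediation_analysis(fit_h, em, y_half, cbind(iq = m_half))
  expect_equal(md_h$table$attenuation_pct[1], 50, tolerance = 5)
  expect_false(md_h$table$no_direct_effect[1])
  # independent mediator: no attenuation anywhere
  md_i <- mediation_analysis(fit_h, em, y_half, cbind(noise = rnorm(n)))
  expect_lt(abs(md_i$table$attenuation_pct[1]), 5)
  expect_lt(abs(md_i$share_mediated_pct), 5)
  # mediator equal to a model column is refused
  expect_error(mediation_analysis(fit_h, em, y_half,
                                  cbind(m = em$data[, "x"])),
               "identical")
})

test_that("prevalence shift is exact at delta 0 and matches the normal
           closed form", {
  set.seed(37)
  y <- rnorm(5000)
  expect_equal(prevalence_shift(y, 0, 0.10), 0.10)
  # closed-form oracle on the exact standard normal
  expect_equal(prevalence_shift(NULL, 0.5, 0.10, distribution = "normal",
                                mean = 0, sd = 1),
               pnorm(qnorm(0.10) - 0.5), tolerance = 1e-12)
  expect_equal(prevalence_shift(NULL, -0.5, 0.10, distribution = "normal",
                                mean = 0, sd = 1),
               pnorm(qnorm(0.10) + 0.5), tolerance = 1e-12)
  # empirical version approximates the closed form and is monotone
  p_up <- prevalence_shift(y, 0.5, 0.10)
  p_dn <- prevalence_shift(y, -0.5, 0.10)
  expect_lt(abs(p_up - pnorm(qnorm(0.10) - 0.5)), 0.01)
  expect_lt(abs(p_dn - pnorm(qnorm(0.10) + 0.5)), 0.01)
  deltas <- seq(-1, 1, by = 0.25)
  prev <- vapply(deltas, function(d) prevalence_shift(y, d, 0.10),
                 numeric(1))
  expect_true(all(diff(prev) <= 0))       # higher scores, smaller tail
  expect_error(prevalence_shift(y, 100), "range")
})
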