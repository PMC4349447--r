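# Chained-equations imputation and Rubin pooling.

make_miss_world <- function(n = 300, seed = 1, miss = 0.2,
                            mechanism = c("mcar", "mar")) {
  mechanism <- match.arg(mechanism)
  set.seed(seed)
  x1 <- rnorm(n)                        # fully observed anchor
  x2 <- 0.7 * x1 + rnorm(n, sd = sqrt(1 - 0.49))
  x3 <- rnorm(n)
  y <- 0.8 * x2 + 0.4 * x3 + rnorm(n)
  X <- cbind(x1 = x1, x2 = x2, x3 = x3)
  if (mechanism == "mcar") {
    X[runif(n) < miss, "x2"] <- NA
    X[runif(n) < miss, "x3"] <- NA
  } else {
    X[plogis(-1 + 1.5 * x1) > runif(n), "x2"] <- NA
  }
  list(em = as_em(X), y = y, x2_true = x2)
}

test_that("zero missingness returns the input for any M", {
  w <- make_miss_world(miss = 0)
  w$em$data[] <- round(w$em$data, 6)
  imp <- mice_impute(w$em, w$y, M = 3, n_iter = 2, seed = 1)
  for (i in 1:3)
    expect_identical(complete_data(imp, i)$data, w$em$data)
})

test_that("observed cells are never altered and seeds reproduce chains", {
  w <- make_miss_world(seed = 2)
  obs <- !is.na(w$em$data)
  imp <- mice_impute(w$em, w$y, M = 2, n_iter = 3, seed = 7)
  for (i in 1:2) {
    comp <- complete_data(imp, i)$data
    expect_identical(comp[obs], w$em$data[obs])
    expect_false(anyNA(comp))
  }
  imp2 <- mice_impute(w$em, w$y, M = 2, n_iter = 3, seed = 7)
  expect_identical(complete_data(imp, 1)$data, complete_data(imp2, 1)$data)
  expect_error(mice_impute(as_em(matrix(NA_real_, 10, 1)), rnorm(10)),
               "100%")
})

test_that("MAR imputations track the anchor-conditional mean", {
  # x2 | x1 ~ N(0.7 x1, 0.51); under MAR-given-x1 the imputed cells should
  # reproduce that conditional structure (given x1 and the other predictors)
  w <- make_miss_world(n = 2000, seed = 3, mechanism = "mar")
  imp <- mice_impute(w$em, w$y, M = 5, n_iter = 8, seed = 11)
  mis <- is.na(w$em$data[, "x2"])
  err <- rowMeans(sapply(1:5, function(i)
    complete_data(imp, i)$data[mis, "x2"])) - w$x2_true[mis]
  # no systematic bias relative to the truth on the missing cells
  expect_lt(abs(mean(err)), 0.1)
  # imputed values follow the anchor gradient
  fit <- lm(complete_data(imp, 1)$data[mis, "x2"] ~ w$em$data[mis, "x1"])
  expect_gt(coef(fit)[2], 0.3)
})

test_that("binary and ordinal conditionals respect their supports", {
  set.seed(4)
  n <- 400
  z <- rnorm(n)
  xb <- as.numeric(z + rnorm(n) > 0)
  xo <- findInterval(z + rnorm(n), c(-1, 0, 1))
  xc <- rnorm(n)
  X <- cbind(b = xb, o = xo, c = xc)
  X[runif(n) < 0.25, "b"] <- NA
  X[runif(n) < 0.25, "o"] <- NA
  cb <- exposure_codebook(c("b", "o", "c"), "health",
                          var_type = c("binary", "ordinal", "continuous"))
  em <- exposome_matrix(X, cb)
  y <- z + rnorm(n)
  imp <- mice_impute(em, y, M = 2, n_iter = 5, seed = 5)
  for (i in 1:2) {
    comp <- complete_data(imp, i)$data
    expect_true(all(comp[, "b"] %in% c(0, 1)))
    expect_true(all(comp[, "o"] %in% 0:3))   # PMM draws observed values
  }
  expect_identical(unname(imp$methods[c("b", "o")]), c("logreg", "pmm"))
})

test_that("pool_rubin follows the textbook arithmetic", {
  # M = 1: unchanged
  w <- make_miss_world(seed = 6)
  imp <- mice_impute(w$em, w$y, M = 1, n_iter = 3, seed = 1)
  f1 <- refit_model(complete_data(imp, 1), w$y, c("x1", "x2"))
  expect_identical(pool_rubin(list(f1)), f1)
  # identical fits: between-variance 0, pooled SE = within SE
  pooled_same <- pool_rubin(list(f1, f1, f1))
  i <- match("x2", pooled_same$table$term)
  expect_equal(pooled_same$table$se[i], f1$table$se[i], tolerance = 1e-12)
  expect_equal(pooled_same$pooling$between, rep(0, nrow(f1$table)))
  # hand-computed 2-imputation case (oracle = Rubin's formulas)
  imp2 <- mice_impute(w$em, w$y, M = 2, n_iter = 3, seed = 2)
  fits <- lapply(1:2, function(i)
    refit_model(complete_data(imp2, i), w$y, c("x1", "x2")))
  pooled <- pool_rubin(fits)
  q <- sapply(fits, function(f) f$table$B[1])
  u <- sapply(fits, function(f) f$table$se[1]^2)
  Bv <- var(q); W <- mean(u); Tv <- W + 1.5 * Bv
  expect_equal(pooled$table$B[1], mean(q), tolerance = 1e-12)
  expect_equal(pooled$table$se[1], sqrt(Tv), tolerance = 1e-12)
  lam <- 1.5 * Bv / Tv
  nu_old <- 1 / lam^2
  dfc <- fits[[1]]$df
  nu_obs <- (dfc + 1) / (dfc + 3) * dfc * (1 - lam)
  expect_equal(pooled$pooling$df[1], nu_old * nu_obs / (nu_old + nu_obs),
               tolerance = 1e-9)
  # mismatched variable sets refuse to pool
  f_other <- refit_model(complete_data(imp2, 1), w$y, "x1")
  expect_error(pool_rubin(list(fits[[1]], f_other)), "mismatch")
})

test_that("between-imputation variance grows with the missing rate", {
  bvar <- vapply(c(0.05, 0.2, 0.4), function(rate) {
    mean(vapply(1:4, function(s) {
      w <- make_miss_world(n = 250, seed = 100 + s * 7 + round(rate * 100),
                           miss = rate)
      imp <- mice_impute(w$em, w$y, M = 4, n_iter = 4, seed = s)
      fits <- lapply(1:4, function(i)
        refit_model(complete_data(imp, i), w$y, c("x1", "x2", "x3")))
      mean(pool_rubin(fits)$pooling$between)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(bvar) > 0))
})
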