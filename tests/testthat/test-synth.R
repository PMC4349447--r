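# Synthetic exposome generator: spec validation, marginal structure,
# planted-effect calibration, reproducibility, missingness mechanisms.

test_that("spec validation rejects impossible worlds", {
  expect_error(synthetic_spec(within_domain_corr = 0.2,
                              cross_domain_corr = 0.5),
               "positive definite")
  expect_error(synthetic_spec(within_domain_corr = 1.0),
               "positive definite")
  pe <- data.frame(id = c(3L, 3L), beta = c(0.5, 0.6))
  expect_error(synthetic_spec(n_variables = 60, planted_effects = pe),
               "twice")
  pe2 <- data.frame(id = 700L, beta = 0.5)
  expect_error(synthetic_spec(n_variables = 60, planted_effects = pe2),
               "1..n_variables", fixed = TRUE)
  expect_error(synthetic_spec(missing_rate = 1.2), "missing_rate")
})

test_that("null world has near-zero univariable slopes and bounded outcome", {
  spec <- synthetic_spec(n_subjects = 1500, n_variables = 40,
                         planted_effects = data.frame(id = integer(0),
                                                      beta = numeric(0)),
                         missing_rate = 0, partnerless_rate = 0, seed = 11)
  g <- generate_exposome(spec)
  expect_true(all(g$outcome >= 126 & g$outcome <= 232))
  em <- standardize(g$matrix)
  scan <- univariable_scan(em, g$outcome)
  # mean slope across variables ~ 0 (each slope has SE ~ sd(y)/sqrt(n))
  expect_lt(abs(mean(scan$B)), 3 * sd(g$outcome) / sqrt(1500))
  # left skew from the sinh-arcsinh noise
  y <- g$outcome
  expect_lt(mean(((y - mean(y)) / sd(y))^3), 0)
})

test_that("a single planted effect is recovered within 3 SE by OLS", {
  spec <- synthetic_spec(n_subjects = 5000, n_variables = 30,
                         within_domain_corr = 0, cross_domain_corr = 0,
                         planted_effects = data.frame(id = 4L, beta = 0.6),
                         outcome_skew = 0, missing_rate = 0,
                         partnerless_rate = 0, seed = 21)
  g <- generate_exposome(spec)
  em <- standardize(g$matrix)
  scan <- univariable_scan(em, g$outcome)
  i <- which(scan$name == g$truth$planted_effects$name)
  # closed-form SE of the standardized univariable slope
  se_oracle <- sd(g$outcome) / sqrt(5000)
  expect_lt(abs(scan$B[i] - 0.6), 3 * se_oracle)
  expect_equal(scan$B[i], scan$B[i], tolerance = 0)  # deterministic rerun below
  g2 <- generate_exposome(spec)
  expect_identical(g$matrix$data, g2$matrix$data)
})

test_that("latent block correlation matches targets within/across domains", {
  spec <- synthetic_spec(n_subjects = 4000, n_variables = 40, n_domains = 4,
                         within_domain_corr = 0.5, cross_domain_corr = 0.1,
                         planted_effects = data.frame(id = integer(0),
                                                      beta = numeric(0)),
                         missing_rate = 0, partnerless_rate = 0, seed = 5)
  g <- generate_exposome(spec)
  R <- cor(g$latent)
  dom <- rep(1:4, each = 10)
  same <- outer(dom, dom, "==") & upper.tri(R)
  diff <- outer(dom, dom, "!=") & upper.tri(R)
  expect_equal(mean(R[same]), 0.5, tolerance = 0.05)
  expect_equal(mean(R[diff]), 0.1, tolerance = 0.05)
  expect_gt(mean(R[same]), mean(R[diff]))
})

test_that("truth record regenerates the dataset bit-identically and
           round-trips through JSON", {
  spec <- synthetic_spec(n_subjects = 300, n_variables = 40,
                         missing_rate = 0.1, seed = 9)
  g <- generate_exposome(spec)
  g2 <- regenerate_exposome(g$truth)
  expect_identical(g$matrix$data, g2$matrix$data)
  expect_identical(g$outcome, g2$outcome)
  path <- tempfile(fileext = ".json")
  write_truth_record(g$truth, path)
  tr <- read_truth_record(path)
  g3 <- regenerate_exposome(tr)
  expect_identical(g$matrix$data, g3$matrix$data)
  expect_identical(g$truth$planted_effects$beta, tr$planted_effects$beta)
})

test_that("MCAR missingness is independent of the anchor variables", {
  # chi-squared independence between missingness of one column and a
  # median split of another fully observed column, over repeated seeds:
  # rejections at the 5% level should occur at roughly the nominal rate
  rej <- vapply(1:40, function(s) {
    spec <- synthetic_spec(n_subjects = 600, n_variables = 20,
                           planted_effects = data.frame(id = integer(0),
                                                        beta = numeric(0)),
                           missing_rate = 0.2,
                           missing_mechanism = "MCAR",
                           partnerless_rate = 0, seed = s)
    g <- generate_exposome(spec)
    m1 <- is.na(g$matrix$data[, 3])
    x2 <- g$latent[, 10]
    suppressWarnings(chisq.test(table(m1, x2 > median(x2)))$p.value) < 0.05
  }, logical(1))
  expect_lt(mean(rej), 0.20)  # nominal 5%, binomial slack at 40 replicates
})

test_that("MAR missingness depends on its domain anchors", {
  spec <- synthetic_spec(n_subjects = 4000, n_variables = 40, n_domains = 4,
                         planted_effects = data.frame(id = integer(0),
                                                      beta = numeric(0)),
                         missing_rate = 0.25, missing_mechanism = "MAR",
                         partnerless_rate = 0, seed = 31)
  g <- generate_exposome(spec)
  a <- g$truth$anchor_ids[1:2]        # anchors of domain 1 (vars 1..10)
  target <- setdiff(1:10, a)[1]
  expect_true(all(!is.na(g$matrix$data[, a])))  # anchors fully observed
  s <- 0.5 * g$latent[, a[1]] + 0.5 * g$latent[, a[2]]
  miss <- is.na(g$matrix$data[, target])
  expect_gt(mean(s[miss]), mean(s[!miss]))      # missingness tracks anchors
  expect_equal(mean(miss), 0.25, tolerance = 0.05)
})

test_that("null p-value generator is uniform, reproducible, and guarded", {
  expect_error(generate_null_pvalue_set(0), ">= 1")
  expect_identical(generate_null_pvalue_set(10, seed = 3),
                   generate_null_pvalue_set(10, seed = 3))
  p <- generate_null_pvalue_set(10000, seed = 4)
  expect_gt(stats::ks.test(p, "punif")$p.value, 1e-4)
})

test_that("partnerless subjects lack all partner-reported variables", {
  spec <- synthetic_spec(n_subjects = 1000, n_variables = 40,
                         missing_rate = 0, partnerless_rate = 0.05,
                         seed = 13)
  g <- generate_exposome(spec)
  pv <- g$matrix$codebook$reporter == "partner"
  pl <- g$matrix$partner_status == 1
  expect_equal(sum(pl), 50)
  expect_true(all(is.na(g$matrix$data[pl, pv])))
  expect_true(!anyNA(g$matrix$data[!pl, pv]))
})
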