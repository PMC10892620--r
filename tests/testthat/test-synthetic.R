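test_that("zero-noise data give exact coefficient recovery", {
  spec <- synthetic_spec(n = 30, p = 5, beta = c(0.5, 1, -2, 0.3, 0, 4),
                         noise_sd = 0, seed = 101)
  d <- generate_qsar_data(spec)
  fit <- fit_qsar(d, spec$descriptor_names)
  expect_equal(unname(coef(fit)), spec$beta, tolerance = 1e-8)
  expect_equal(fit$rss, 0, tolerance = 1e-12)
})

test_that("generation is deterministic under a fixed seed", {
  spec <- synthetic_spec(n = 20, p = 3, beta = c(0, 1, 1, 1), seed = 55)
  expect_identical(generate_qsar_data(spec), generate_qsar_data(spec))
  d2 <- generate_qsar_data(spec, seed = 56)
  expect_false(identical(generate_qsar_data(spec), d2))
})

test_that("spec invariants are enforced", {
  expect_error(synthetic_spec(n = 12, p = 10, beta = rep(0, 11)), "n > p \\+ 2")
  expect_error(synthetic_spec(n = 30, p = 3, beta = rep(0, 3)), "length p \\+ 1")
  expect_error(synthetic_spec(n = 30, p = 3, beta = rep(0, 4), correlation = 1),
               "\\[0, 1\\)")
  expect_error(synthetic_spec(n = 30, p = 3, beta = rep(0, 4), noise_sd = -1),
               ">= 0")
  expect_error(synthetic_spec(n = 30, p = 3, beta = rep(0, 4),
                              descriptor_sds = c(1, 0, 1)), "positive")
})

test_that("descriptor scales and correlation shape the generated columns", {
  spec <- synthetic_spec(n = 2000, p = 3, beta = rep(0, 4),
                         descriptor_means = c(10, -5, 1000),
                         descriptor_sds = c(2, 0.1, 300),
                         correlation = 0.5, noise_sd = 1, seed = 77)
  d <- generate_qsar_data(spec)
  X <- as.matrix(d[spec$descriptor_names])
  expect_equal(unname(colMeans(X)), c(10, -5, 1000), tolerance = 0.1)
  expect_equal(unname(apply(X, 2, sd)), c(2, 0.1, 300), tolerance = 0.1)
  cors <- cor(scale(X))
  expect_equal(unname(cors[upper.tri(cors)]), rep(0.5, 3), tolerance = 0.1)
})

test_that("coefficient estimates are unbiased at moderate noise (Monte Carlo)", {
  spec <- synthetic_spec(n = 27, p = 10, beta = c(1, rnorm(10)), noise_sd = 1,
                         seed = NULL)
  withr::local_seed(202)
  reps <- 300
  est <- matrix(NA_real_, reps, 11)
  for (i in seq_len(reps)) {
    d <- generate_qsar_data(spec, seed = NULL)
    est[i, ] <- coef(fit_qsar(d, spec$descriptor_names))
  }
  mc_se <- apply(est, 2, sd) / sqrt(reps)
  bias <- colMeans(est) - spec$beta
  expect_true(all(abs(bias) < 3.5 * mc_se))
})

test_that("the fixture-mimicking spec has the right shape and behaviour", {
  spec <- ptp1b_mimic_spec()
  expect_equal(spec$n, 27L)
  expect_equal(spec$p, 10L)
  expect_equal(spec$descriptor_names, ptp1b_model_descriptors())
  d <- ptp1b_tzd()
  expect_equal(spec$descriptor_means,
               unname(vapply(d[spec$descriptor_names], mean, numeric(1))))
  # refit R2 lands in a plausible band across seeds
  r2 <- vapply(1:20, function(s) {
    g <- generate_qsar_data(spec, seed = s)
    glance(fit_qsar(g, spec$descriptor_names))$r.squared
  }, numeric(1))
  expect_true(all(r2 > 0.7 & r2 < 0.99))
  expect_equal(mean(r2), 0.89, tolerance = 0.05)
  # zero-noise override gives a perfect fit
  g0 <- generate_qsar_data(ptp1b_mimic_spec(noise_sd = 0), seed = 1)
  expect_equal(glance(fit_qsar(g0, spec$descriptor_names))$r.squared, 1)
})

test_that("noisy replicates always have Q2 below R2 and scrambling collapses them", {
  withr::local_seed(303)
  spec <- ptp1b_mimic_spec()
  for (s in 1:5) {
    g <- generate_qsar_data(spec, seed = s)
    v <- validate_qsar(fit_qsar(g, spec$descriptor_names))
    expect_lt(v$q2_loo, v$r2)
  }
  g <- generate_qsar_data(spec, seed = 11)
  yr <- y_randomization(fit_qsar(g, spec$descriptor_names), n_trials = 50, seed = 12)
  expect_lt(abs(yr$mean_r2 - 10 / 26), 0.15)
  expect_gt(yr$crp2$value[yr$crp2$variant == "as_used"], 0.5)
})

test_that("parameter-recovery error shrinks as n grows", {
  withr::local_seed(404)
  rmse_at_n <- function(n, reps = 60) {
    spec <- synthetic_spec(n = n, p = 4, beta = c(1, 2, -1, 0.5, -0.25),
                           noise_sd = 1)
    errs <- replicate(reps, {
      d <- generate_qsar_data(spec, seed = NULL)
      sqrt(mean((coef(fit_qsar(d, spec$descriptor_names)) - spec$beta)^2))
    })
    mean(errs)
  }
  expect_gt(rmse_at_n(15), rmse_at_n(120))
})

test_that("true_beta retrieves the generating coefficients", {
  spec <- synthetic_spec(n = 20, p = 2, beta = c(1, 2, 3), seed = 9)
  d <- generate_qsar_data(spec)
  expect_equal(unname(true_beta(d)), c(1, 2, 3))
  expect_error(true_beta(ptp1b_tzd()), "true coefficient")
})
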