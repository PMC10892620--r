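test_that("simple regression recovers the closed-form slope and intercept", {
  # cov/var oracle for y = 1 + 2x on x = 0:3
  d <- toy_linear()
  fit <- fit_qsar(d, "x")
  slope <- cov(d$x, d$pic50) / var(d$x)
  intercept <- mean(d$pic50) - slope * mean(d$x)
  expect_equal(unname(coef(fit)), c(intercept, slope))
  expect_equal(unname(coef(fit)), c(1, 2))
  expect_equal(fit$rss, 0)
  expect_equal(unname(fit$residuals), rep(0, 4))
  # exact-fit model interpolates its own training rows
  expect_equal(predict(fit, d), fit$fitted)
})

test_that("OLS invariants hold: residual identities, hat trace, orthogonality", {
  withr::local_seed(11)
  for (case in list(c(n = 15, p = 2), c(n = 30, p = 6), c(n = 50, p = 12))) {
    d <- random_problem(case["n"], case["p"])
    desc <- paste0("x", seq_len(case["p"]))
    fit <- fit_qsar(d, desc)
    # fitted + residual = observed
    expect_equal(unname(fit$fitted + fit$residuals), d$pic50, tolerance = 1e-9)
    # residuals sum to zero (intercept model)
    expect_lt(abs(sum(fit$residuals)), 1e-8 * case["n"])
    # hat diagonals in (0,1], summing to p+1
    expect_true(all(fit$hat > 0 & fit$hat <= 1))
    expect_equal(sum(fit$hat), unname(case["p"]) + 1)
    # residuals orthogonal to every design column
    X <- cbind(1, as.matrix(d[desc]))
    expect_lt(max(abs(crossprod(X, fit$residuals))) / sqrt(fit$rss + 1), 1e-8)
  }
})

test_that("coefficients agree with the reference implementation on random instances", {
  withr::local_seed(21)
  for (rep in 1:5) {
    n <- sample(15:50, 1)
    p <- sample(1:12, 1)
    d <- random_problem(n, p)
    desc <- paste0("x", seq_len(p))
    fit <- fit_qsar(d, desc)
    oracle <- lm(reformulate(desc, "pic50"), data = d)
    expect_equal(unname(coef(fit)), unname(coef(oracle)), tolerance = 1e-8)
    expect_equal(unname(fit$hat), unname(lm.influence(oracle)$hat), tolerance = 1e-8)
    expect_equal(fit$rss, sum(resid(oracle)^2), tolerance = 1e-8)
  }
})

test_that("hat diagonals match the explicit matrix product on a 3-point design", {
  d <- tibble::tibble(compound_id = c("a", "b", "c"), pic50 = c(1, 2, 4), x = c(0, 1, 3))
  fit <- fit_qsar(d, "x")
  X <- cbind(1, d$x)
  H <- X %*% solve(t(X) %*% X) %*% t(X)
  expect_equal(unname(fit$hat), unname(diag(H)), tolerance = 1e-12)
})

test_that("fitted values are invariant under affine descriptor rescaling", {
  withr::local_seed(31)
  d <- random_problem(25, 4)
  fit <- fit_qsar(d, paste0("x", 1:4))
  d2 <- dplyr::mutate(d, x2 = 1000 * x2 + 7, x4 = x4 / 1e6)
  fit2 <- fit_qsar(d2, paste0("x", 1:4))
  expect_equal(unname(fit2$fitted), unname(fit$fitted), tolerance = 1e-8)
  # coefficients transform consistently
  expect_equal(unname(coef(fit2)["x2"]), unname(coef(fit)["x2"]) / 1000, tolerance = 1e-8)
  expect_equal(unname(coef(fit2)["x4"]), unname(coef(fit)["x4"]) * 1e6, tolerance = 1e-8)
})

test_that("degenerate designs are rejected with informative errors", {
  withr::local_seed(41)
  d <- random_problem(10, 2)
  # duplicated column => rank deficient, named
  d$x_dup <- d$x1
  expect_error(fit_qsar(d, c("x1", "x2", "x_dup")), "rank deficient")
  # identical rows: constant descriptor is collinear with the intercept
  dconst <- dplyr::mutate(d, x1 = 5)
  expect_error(fit_qsar(dconst, c("x1", "x2")), "rank deficient.*x1")
  # too few compounds
  expect_error(fit_qsar(d[1:3, ], c("x1", "x2")), "Insufficient data")
  # missing descriptor at predict time is named
  fit <- fit_qsar(d, c("x1", "x2"))
  expect_error(predict(fit, d[, c("compound_id", "x1")]), "x2")
  # non-finite values rejected
  dna <- d
  dna$x1[2] <- NA
  expect_error(fit_qsar(dna, c("x1", "x2")), "finite")
})

test_that("broom-style accessors are consistent with the fit", {
  fit <- fit_qsar(ptp1b_tzd(), ptp1b_model_descriptors())
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", ptp1b_model_descriptors()))
  expect_equal(td$estimate, unname(coef(fit)))
  gl <- glance(fit)
  expect_equal(gl$rss, fit$rss)
  expect_equal(gl$n, 27)
  aug <- augment(fit)
  expect_equal(aug$.fitted + aug$.resid, aug$pic50)
  expect_equal(sum(aug$.hat), 11)
})
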