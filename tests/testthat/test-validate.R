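test_that("validation statistics match their defining formulas on a toy problem", {
  withr::local_seed(7)
  d <- random_problem(20, 3)
  fit <- fit_qsar(d, paste0("x", 1:3))
  v <- validate_qsar(fit)
  y <- d$pic50
  n <- 20
  p <- 3
  ssy <- sum((y - mean(y))^2)
  r2 <- 1 - fit$rss / ssy
  expect_equal(v$ssy, ssy)
  expect_equal(v$r2, r2)
  expect_equal(v$r, sqrt(r2))
  expect_equal(v$r2_adj, 1 - (1 - r2) * (n - 1) / (n - p - 1))
  expect_equal(v$see, sqrt(fit$rss / (n - p - 1)))
  expect_equal(v$s_y, sd(y))
  expect_equal(v$f_stat, (r2 / p) / ((1 - r2) / (n - p - 1)))
  expect_equal(v$q_factor, sqrt(r2) / sd(y))
  expect_equal(v$pe, 0.6745 * (1 - r2) / sqrt(n))
  expect_equal(v$six_pe, 6 * v$pe)
  expect_equal(v$press_ratio, fit$rss / ssy)
  expect_equal(v$s_press, v$see)
  expect_equal(v$pse, v$press_loo / n)
  # report invariants
  expect_true(v$r2 >= 0 && v$r2 <= 1)
  expect_lte(v$r2_adj, v$r2)
  expect_gte(v$press_loo, v$rss)
  expect_lte(v$q2_loo, v$r2)
})

test_that("LOO shortcut equals explicit refit-without-i on random instances", {
  withr::local_seed(17)
  for (rep in 1:4) {
    n <- sample(15:40, 1)
    p <- sample(1:8, 1)
    d <- random_problem(n, p)
    fit <- fit_qsar(d, paste0("x", seq_len(p)))
    expect_equal(loo_residuals(fit, "shortcut"), loo_residuals(fit, "refit"),
                 tolerance = 1e-8)
  }
})

test_that("noiseless linear data give PRESS_LOO = 0 and Q2 = 1", {
  withr::local_seed(27)
  d <- random_problem(20, 3, noise_sd = 0)
  expect_warning(v <- validate_qsar(fit_qsar(d, paste0("x", 1:3))), "Perfect fit")
  expect_equal(v$press_loo, 0, tolerance = 1e-12)
  expect_equal(v$q2_loo, 1)
  expect_equal(v$r2, 1)
})

test_that("degenerate cases: constant activity errors, perfect fit flags Inf F", {
  d <- toy_linear()
  dconst <- dplyr::mutate(d, pic50 = 5)
  expect_error(validate_qsar(fit_qsar(dconst, "x")), "SSY = 0")
  expect_warning(v <- validate_qsar(fit_qsar(d, "x"), loo = FALSE), "Perfect fit")
  expect_true(is.infinite(v$f_stat))
  expect_true(v$perfect_fit)
})

test_that("LOO requires every reduced fit to be overdetermined", {
  withr::local_seed(37)
  d <- random_problem(5, 2)
  fit <- fit_qsar(d, c("x1", "x2")) # n = p + 3 ok; shrink below
  expect_error(loo_residuals(fit_qsar(d[1:4, ], "x1"), "shortcut"), NA)
  d4 <- random_problem(4, 2)
  expect_error(loo_residuals(fit_qsar(d4, c("x1", "x2"))), "n > p \\+ 2")
})

test_that("adding pure-noise descriptors never decreases R2 and degrades LOO Q2 on average", {
  withr::local_seed(47)
  diffs_r2 <- diffs_q2 <- numeric(20)
  for (i in 1:20) {
    d <- random_problem(30, 3, noise_sd = 1)
    d <- dplyr::mutate(d, junk1 = rnorm(30), junk2 = rnorm(30), junk3 = rnorm(30))
    v0 <- validate_qsar(fit_qsar(d, paste0("x", 1:3)))
    v1 <- validate_qsar(fit_qsar(d, c(paste0("x", 1:3), paste0("junk", 1:3))))
    diffs_r2[i] <- v1$r2 - v0$r2
    diffs_q2[i] <- v1$q2_loo - v0$q2_loo
  }
  expect_true(all(diffs_r2 >= -1e-12)) # R2 cannot drop when predictors are added
  expect_lt(mean(diffs_q2), 0) # predictive power does drop in expectation
})

test_that("validation report round-trips losslessly through JSON", {
  withr::local_seed(57)
  v <- validate_qsar(fit_qsar(random_problem(20, 3), paste0("x", 1:3)))
  gl <- glance(v)
  json <- jsonlite::toJSON(gl, digits = NA, dataframe = "rows")
  back <- jsonlite::fromJSON(json)
  expect_equal(as.list(back), as.list(as.data.frame(gl)), tolerance = 1e-12)
})
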