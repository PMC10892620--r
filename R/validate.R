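#' QSAR validation statistics for a fitted model
#'
#' Computes the classical goodness-of-fit suite and exact leave-one-out
#' (LOO) cross-validation for an MLR QSAR model:
#'
#' * `ssy = sum((y - mean(y))^2)`, total sum of squares of the activity;
#' * `r2 = 1 - rss/ssy`, `r = sqrt(r2)`,
#'   `r2_adj = 1 - (1 - r2)(n - 1)/(n - p - 1)`;
#' * `see = sqrt(rss/(n - p - 1))`, residual standard error of estimate;
#' * `s_y = sqrt(ssy/(n - 1))`, activity standard deviation;
#' * `f_stat = (r2/p) / ((1 - r2)/(n - p - 1))`, Fisher ratio;
#' * `q_factor = r / s_y`, quality factor;
#' * `pe = 0.6745 (1 - r2)/sqrt(n)`, classical probable error of the
#'   correlation coefficient, and `six_pe = 6 pe` (a model is considered
#'   predictive when `r > six_pe`);
#' * `press_fit = rss` and `press_ratio = rss/ssy`. In much of the QSAR
#'   validation literature these residual-based quantities are tabulated
#'   under the label "PRESS"; both interpretations are therefore reported
#'   (see below). `s_press = sqrt(rss/(n - p - 1))`, numerically identical
#'   to `see`;
#' * `press_loo = sum((y_i - yhat_(-i))^2)` with `yhat_(-i)` predicted by
#'   the model refit without compound `i`, and `q2_loo = 1 - press_loo/ssy`
#'   (also written R2cv). `pse = press_loo/n` is the mean squared LOO
#'   prediction error.
#'
#' The per-compound LOO prediction error is computed with the exact
#' hat-diagonal shortcut `e_i / (1 - h_i)`, which for OLS is
#' algebraically identical to refitting without compound `i`; the explicit
#' n-refit route is available via [loo_residuals()] and used as a
#' cross-check in the package tests.
#'
#' @param fit A [fit_qsar()] model.
#' @param loo Compute the leave-one-out fields (default `TRUE`); requires
#'   `n > p + 2`.
#' @return An object of class `qsar_validation`: a list of the statistics
#'   above plus `n`, `p` and a `perfect_fit` flag. When `rss == 0` the
#'   Fisher ratio is reported as `Inf` with a warning rather than an
#'   error.
#' @seealso [loo_residuals()], [glance.qsar_validation()]
#' @examples
#' v <- validate_qsar(fit_qsar(ptp1b_tzd(), ptp1b_model_descriptors()))
#' glance(v)
#' @export
validate_qsar <- function(fit, loo = TRUE) {
  stopifnot(inherits(fit, "qsar_fit"))
  y <- fit$fitted + fit$residuals
  n <- fit$n
  p <- fit$p
  ssy <- sum((y - mean(y))^2)
  if (ssy == 0) {
    abort("Degenerate response: activity is constant (SSY = 0).")
  }
  rss <- fit$rss
  r2 <- 1 - rss / ssy
  dfres <- n - p - 1
  perfect <- rss <= 1e-20 * ssy # exact interpolation up to roundoff
  f_stat <- if (perfect) {
    warn("Perfect fit (RSS = 0): Fisher ratio reported as Inf.")
    Inf
  } else {
    (r2 / p) / ((1 - r2) / dfres)
  }
  pe <- 0.6745 * (1 - r2) / sqrt(n)
  out <- list(
    r = sqrt(r2),
    r2 = r2,
    r2_adj = 1 - (1 - r2) * (n - 1) / dfres,
    see = sqrt(rss / dfres),
    s_y = sqrt(ssy / (n - 1)),
    f_stat = f_stat,
    q_factor = sqrt(r2) / sqrt(ssy / (n - 1)),
    pe = pe,
    six_pe = 6 * pe,
    ssy = ssy,
    rss = rss,
    press_fit = rss,
    press_ratio = rss / ssy,
    s_press = sqrt(rss / dfres),
    press_loo = NA_real_,
    q2_loo = NA_real_,
    pse = NA_real_,
    n = n,
    p = p,
    perfect_fit = perfect
  )
  if (loo) {
    e_loo <- loo_residuals(fit, method = "shortcut")
    out$press_loo <- sum(e_loo^2)
    out$q2_loo <- 1 - out$press_loo / ssy
    out$pse <- out$press_loo / n
  }
  structure(out, class = "qsar_validation")
}

#' Leave-one-out prediction residuals
#'
#' For each compound `i`, the error of predicting its activity from the
#' model refit on the remaining `n - 1` compounds. Two routes:
#' `"shortcut"` uses the exact OLS identity `e_i / (1 - h_i)`;
#' `"refit"` performs the `n` explicit refits. The two agree to machine
#' precision and the refit route exists as an independent check.
#'
#' @param fit A [fit_qsar()] model with `n > p + 2`.
#' @param method `"shortcut"` (default) or `"refit"`.
#' @return Named numeric vector of LOO prediction residuals.
#' @export
loo_residuals <- function(fit, method = c("shortcut", "refit")) {
  stopifnot(inherits(fit, "qsar_fit"))
  method <- match.arg(method)
  if (fit$n <= fit$p + 2) {
    abort("Leave-one-out requires n > p + 2 so every reduced fit is overdetermined.")
  }
  if (method == "shortcut") {
    return(fit$residuals / (1 - fit$hat))
  }
  des <- check_design(fit$data, fit$descriptors, fit$activity, fit$id)
  X <- des$X
  y <- des$y
  out <- vapply(seq_len(fit$n), function(i) {
    sub <- tryCatch(
      ols_qr(X[-i, , drop = FALSE], y[-i]),
      error = function(e) abort(sprintf(
        "Reduced design is singular when leaving out compound '%s': %s",
        des$ids[i], conditionMessage(e)
      ))
    )
    y[i] - drop(X[i, ] %*% sub$coefficients)
  }, numeric(1))
  setNames(out, des$ids)
}

#' @export
print.qsar_validation <- function(x, digits = 3, ...) {
  cat(sprintf(
    "QSAR validation (n = %d, p = %d)\n  R = %.*f  R2 = %.*f  R2adj = %.*f  F = %.*f\n",
    x$n, x$p, digits, x$r, digits, x$r2, digits, x$r2_adj, digits, x$f_stat
  ))
  cat(sprintf(
    "  SEE = %.*f  S_y = %.*f  Q = %.*f  PE = %.*f  6PE = %.*f\n",
    digits, x$see, digits, x$s_y, digits, x$q_factor, digits, x$pe, digits, x$six_pe
  ))
  cat(sprintf(
    "  SSY = %.*f  RSS = %.*f  RSS/SSY = %.*f  S_PRESS = %.*f\n",
    digits, x$ssy, digits, x$rss, digits, x$press_ratio, digits, x$s_press
  ))
  if (!is.na(x$q2_loo)) {
    cat(sprintf("  LOO: PRESS = %.*f  Q2 = %.*f  PSE = %.*f\n",
                digits, x$press_loo, digits, x$q2_loo, digits, x$pse))
  }
  invisible(x)
}

#' One-row tibble of validation statistics
#'
#' @param x A [validate_qsar()] report.
#' @param ... Unused.
#' @return A tibble with one row and one column per statistic.
#' @method glance qsar_validation
#' @export
glance.qsar_validation <- function(x, ...) {
  as_tibble(x[c(
    "r", "r2", "r2_adj", "see", "s_y", "f_stat", "q_factor", "pe", "six_pe",
    "ssy", "rss", "press_ratio", "s_press", "press_loo", "q2_loo", "pse",
    "n", "p"
  )])
}
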