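#' Fit an MLR QSAR model by ordinary least squares
#'
#' Regresses an activity column on a set of descriptor columns with an
#' intercept. The solver is a Householder QR decomposition of the
#' intercept-augmented design matrix; coefficients are obtained by
#' back-substitution and the hat-matrix diagonals (leverages) as the row
#' sums of squares of the thin Q factor. No standardization is applied:
#' coefficients are reported on the raw descriptor scales, which for
#' typical descriptor tables span many orders of magnitude (topological
#' indices ~1e6 against partial charges ~1e-1) -- the orthogonal
#' decomposition keeps the solution numerically stable on such designs.
#'
#' The design must have full column rank: singular values below
#' `1e-10` times the largest singular value declare rank deficiency, and
#' the error names the offending column(s). At least `p + 2` compounds are
#' required for `p` descriptors.
#'
#' @param data A data frame with one row per compound.
#' @param descriptors Character vector of descriptor column names to use as
#'   predictors.
#' @param activity Name of the activity column (default `"pic50"`).
#' @param id Name of the compound-identifier column (default
#'   `"compound_id"`).
#' @return An object of class `qsar_fit`: a list with elements
#'   `coefficients` (named, intercept first), `fitted`, `residuals`, `hat`
#'   (all named by compound id), `rss`, `n`, `p`, `descriptors`,
#'   `activity`, `id`, `data` (the training table) and `qr_r` (the upper
#'   triangular R factor, used for leverages of new compounds).
#' @seealso [validate_qsar()], [assess_domain()], [y_randomization()],
#'   [screen_candidates()].
#' @examples
#' fit <- fit_qsar(ptp1b_tzd(), ptp1b_model_descriptors())
#' tidy(fit)
#' glance(fit)
#' @export
fit_qsar <- function(data, descriptors, activity = "pic50", id = "compound_id") {
  des <- check_design(data, descriptors, activity, id)
  fit <- ols_qr(des$X, des$y)
  structure(
    list(
      coefficients = fit$coefficients,
      fitted = setNames(fit$fitted, des$ids),
      residuals = setNames(fit$residuals, des$ids),
      hat = setNames(fit$hat, des$ids),
      rss = fit$rss,
      n = nrow(des$X),
      p = length(descriptors),
      descriptors = descriptors,
      activity = activity,
      id = id,
      data = as_tibble(data),
      qr_r = fit$qr_r
    ),
    class = "qsar_fit"
  )
}

# Core OLS on an intercept-augmented design matrix X (first column all 1s).
# Householder QR; rank checked against the singular-value spectrum.
ols_qr <- function(X, y, rank_tol = 1e-10) {
  n <- nrow(X)
  k <- ncol(X)
  if (n <= k) {
    abort(sprintf(
      "Insufficient data: %d compounds for %d predictors + intercept (need n > p + 1).",
      n, k - 1L
    ))
  }
  sv <- svd(X, nu = 0, nv = 0)$d
  if (min(sv) < rank_tol * max(sv)) {
    # identify offending columns via pivoted QR
    qp <- qr(X, tol = 1e-10)
    bad <- if (qp$rank < k) colnames(X)[qp$pivot[(qp$rank + 1):k]] else colnames(X)
    abort(sprintf(
      "Design matrix is rank deficient (singular); offending column(s): %s.",
      paste(bad, collapse = ", ")
    ))
  }
  dec <- qr(X)
  Q <- qr.Q(dec)[, seq_len(k), drop = FALSE]
  R <- qr.R(dec)[seq_len(k), , drop = FALSE]
  coef <- backsolve(R, crossprod(Q, y))
  coef <- setNames(drop(coef), colnames(X))
  fitted <- drop(X %*% coef)
  resid <- y - fitted
  list(
    coefficients = coef,
    fitted = fitted,
    residuals = resid,
    hat = rowSums(Q^2),
    rss = sum(resid^2),
    qr_r = R
  )
}

#' Predict activity for new compounds
#'
#' Evaluates `intercept + sum(coefficient * descriptor)` on the rows of
#' `newdata`. Every model descriptor must be present; a missing one raises
#' an error naming it.
#'
#' @param object A [fit_qsar()] model.
#' @param newdata A data frame carrying the model's descriptor columns.
#'   Defaults to the training data.
#' @param ... Unused.
#' @return Numeric vector of predicted activities, named by compound id
#'   when the id column is present.
#' @export
predict.qsar_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    return(object$fitted)
  }
  X <- new_design(object, newdata)
  pred <- drop(X %*% object$coefficients)
  if (object$id %in% names(newdata)) {
    names(pred) <- as.character(newdata[[object$id]])
  }
  pred
}

# Intercept-augmented design rows for new data, validated against the fit.
new_design <- function(fit, newdata) {
  if (!is.data.frame(newdata)) abort("`newdata` must be a data frame.")
  missing_desc <- setdiff(fit$descriptors, names(newdata))
  if (length(missing_desc) > 0) {
    abort(sprintf("Missing model descriptor(s): %s.",
                  paste(missing_desc, collapse = ", ")))
  }
  Xd <- as.matrix(newdata[, fit$descriptors, drop = FALSE])
  if (!is.numeric(Xd) || any(!is.finite(Xd))) {
    abort("Descriptor values must be finite numerics.")
  }
  cbind(`(Intercept)` = 1, Xd)
}

#' Hat-matrix diagonals (leverages) of a fitted model
#'
#' The leverages `h_i = x_i' (X'X)^-1 x_i` with `x_i` the
#' intercept-augmented descriptor row of compound `i`. Each `h_i` lies in
#' (0, 1] and the leverages sum to `p + 1`.
#'
#' @param fit A [fit_qsar()] model.
#' @return Named numeric vector of leverages.
#' @export
hat_diagonals <- function(fit) {
  stopifnot(inherits(fit, "qsar_fit"))
  fit$hat
}

#' @export
print.qsar_fit <- function(x, ...) {
  cat(sprintf("MLR QSAR fit: %s ~ %d descriptors, n = %d\n",
              x$activity, x$p, x$n))
  print(round(x$coefficients, 6))
  cat(sprintf("RSS = %.6g\n", x$rss))
  invisible(x)
}

#' @describeIn fit_qsar Coefficients as a tibble with columns `term` and
#'   `estimate`.
#' @param x,object A `qsar_fit` object.
#' @param ... Unused.
#' @method tidy qsar_fit
#' @export
tidy.qsar_fit <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' @describeIn fit_qsar One-row tibble of fit summaries (`r.squared`,
#'   `adj.r.squared`, `sigma`, `statistic`, `rss`, `ssy`, `n`, `p`).
#' @method glance qsar_fit
#' @export
glance.qsar_fit <- function(x, ...) {
  y <- x$fitted + x$residuals
  ssy <- sum((y - mean(y))^2)
  r2 <- 1 - x$rss / ssy
  dfres <- x$n - x$p - 1
  tibble(
    r.squared = r2,
    adj.r.squared = 1 - (1 - r2) * (x$n - 1) / dfres,
    sigma = sqrt(x$rss / dfres),
    statistic = (r2 / x$p) / ((1 - r2) / dfres),
    rss = x$rss,
    ssy = ssy,
    n = x$n,
    p = x$p
  )
}

#' @describeIn fit_qsar Training table augmented with `.fitted`, `.resid`,
#'   `.hat` and `.std.resid` columns.
#' @method augment qsar_fit
#' @export
augment.qsar_fit <- function(x, ...) {
  see <- sqrt(x$rss / (x$n - x$p - 1))
  dplyr::mutate(
    x$data,
    .fitted = unname(x$fitted),
    .resid = unname(x$residuals),
    .hat = unname(x$hat),
    .std.resid = if (see > 0) unname(x$residuals) / see else NA_real_
  )
}
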