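#' Warning leverage of the applicability domain
#'
#' The leverage threshold `h* = m (p + 1) / n` beyond which a compound is
#' considered chemically remote from the training set. The multiplier `m`
#' defaults to 2.5; 3 is the other common convention.
#'
#' @param p Number of model descriptors (>= 0).
#' @param n Number of training compounds (> 0).
#' @param multiplier Threshold multiplier (default 2.5).
#' @return The warning leverage, a positive scalar.
#' @examples
#' warning_leverage(10, 27) # ~1.019
#' @export
warning_leverage <- function(p, n, multiplier = 2.5) {
  if (!is.numeric(n) || n <= 0 || !is.numeric(p) || p < 0) {
    abort("Require n > 0 and p >= 0.")
  }
  multiplier * (p + 1) / n
}

#' Leverage-based applicability domain of a fitted model
#'
#' Builds the Williams-plot table for the training set: per-compound
#' leverage (hat diagonal) against standardized residual, with flags for
#' leverage above the warning threshold `h*` and for residuals outside the
#' `+/- residual_band` band. Standardized residuals divide by the residual
#' standard error of the fit; set `studentized = TRUE` to divide instead by
#' `see * sqrt(1 - h_i)` (internally studentized residuals).
#'
#' @param fit A [fit_qsar()] model.
#' @param residual_band Half-width of the acceptable standardized-residual
#'   band, in standard units (default 3).
#' @param hstar_multiplier Multiplier of [warning_leverage()] (default
#'   2.5).
#' @param studentized Use internally studentized residuals (default
#'   `FALSE`).
#' @return An object of class `qsar_domain`: a tibble with columns
#'   `compound_id`, `leverage`, `std_residual`, `high_leverage`,
#'   `residual_outlier`, carrying attributes `h_star`, `residual_band`,
#'   `see` and `degenerate` (TRUE when the fit is perfect and standardized
#'   residuals are undefined).
#' @seealso [autoplot.qsar_domain()] for the Williams plot,
#'   [assess_new_compounds()] for candidate compounds.
#' @examples
#' dom <- assess_domain(fit_qsar(ptp1b_tzd(), ptp1b_model_descriptors()))
#' attr(dom, "h_star")
#' sum(dom$high_leverage | dom$residual_outlier)
#' @export
assess_domain <- function(fit, residual_band = 3, hstar_multiplier = 2.5,
                          studentized = FALSE) {
  stopifnot(inherits(fit, "qsar_fit"))
  h_star <- warning_leverage(fit$p, fit$n, hstar_multiplier)
  see <- sqrt(fit$rss / (fit$n - fit$p - 1))
  y <- fit$fitted + fit$residuals
  degenerate <- fit$rss <= 1e-20 * sum((y - mean(y))^2)
  if (degenerate) {
    warn("Perfect fit: standardized residuals are undefined (reported as NA).")
    std_res <- rep(NA_real_, fit$n)
  } else {
    denom <- if (studentized) see * sqrt(1 - fit$hat) else see
    std_res <- unname(fit$residuals) / denom
  }
  out <- tibble(
    compound_id = names(fit$hat),
    leverage = unname(fit$hat),
    std_residual = std_res,
    high_leverage = unname(fit$hat) > h_star,
    residual_outlier = !is.na(std_res) & abs(std_res) > residual_band
  )
  structure(out,
            class = c("qsar_domain", class(out)),
            h_star = h_star, residual_band = residual_band,
            see = see, degenerate = degenerate)
}

#' Applicability-domain check for new compounds
#'
#' Computes the leverage of each new descriptor row against the training
#' design, `h = x' (X'X)^-1 x` with `x` intercept-augmented, and flags the
#' compound in-domain when `h <= h*`. The leverage of the training
#' descriptor centroid is exactly `1/n`; rows far outside the training
#' cloud exceed `h*`.
#'
#' @param fit A [fit_qsar()] model.
#' @param newdata Data frame with the model's descriptor columns.
#' @param hstar_multiplier Multiplier of [warning_leverage()] (default
#'   2.5).
#' @return A tibble with columns `compound_id` (when present in
#'   `newdata`), `leverage` and `in_domain`.
#' @export
assess_new_compounds <- function(fit, newdata, hstar_multiplier = 2.5) {
  stopifnot(inherits(fit, "qsar_fit"))
  X <- new_design(fit, newdata)
  h_star <- warning_leverage(fit$p, fit$n, hstar_multiplier)
  # h = || R^-T x ||^2 from the training QR factor R
  U <- backsolve(fit$qr_r, t(X), transpose = TRUE)
  lev <- colSums(U^2)
  out <- tibble(leverage = unname(lev), in_domain = unname(lev) <= h_star)
  if (fit$id %in% names(newdata)) {
    out <- dplyr::bind_cols(
      tibble(compound_id = as.character(newdata[[fit$id]])), out
    )
  }
  out
}
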