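#' Specification for a synthetic QSAR dataset
#'
#' Describes a simulated descriptor/activity table: `p` continuous
#' descriptors drawn from a correlated Gaussian (exchangeable pairwise
#' correlation, per-descriptor location and scale), and activity generated
#' by a known linear model plus Gaussian noise. Heterogeneous scales mimic
#' real descriptor tables where topological indices dwarf partial charges
#' by six orders of magnitude.
#'
#' @param n Number of compounds; must exceed `p + 2`.
#' @param p Number of descriptors.
#' @param beta Numeric vector of length `p + 1`: intercept followed by the
#'   true descriptor coefficients.
#' @param descriptor_means,descriptor_sds Length-`p` location and scale of
#'   the descriptor columns (defaults: 0 and 1).
#' @param correlation Exchangeable pairwise descriptor correlation in
#'   `[0, 1)` (default 0.3).
#' @param noise_sd Standard deviation of the activity noise (>= 0).
#' @param descriptor_names Optional length-`p` names (default
#'   `d1 ... dp`).
#' @param seed Integer RNG seed stored in the spec and used by
#'   [generate_qsar_data()] unless overridden.
#' @return An object of class `synthetic_spec`.
#' @seealso [generate_qsar_data()], [ptp1b_mimic_spec()]
#' @export
synthetic_spec <- function(n, p, beta, descriptor_means = rep(0, p),
                           descriptor_sds = rep(1, p), correlation = 0.3,
                           noise_sd = 1, descriptor_names = NULL, seed = NULL) {
  if (!is.numeric(n) || !is.numeric(p) || n <= p + 2) {
    abort("Require n > p + 2 so that fits and leave-one-out are overdetermined.")
  }
  if (length(beta) != p + 1) abort("`beta` must have length p + 1 (intercept first).")
  if (length(descriptor_means) != p || length(descriptor_sds) != p) {
    abort("`descriptor_means` and `descriptor_sds` must have length p.")
  }
  if (any(descriptor_sds <= 0)) abort("Descriptor scales must be positive.")
  if (!is.numeric(correlation) || correlation < 0 || correlation >= 1) {
    abort("`correlation` must lie in [0, 1).")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) abort("`noise_sd` must be >= 0.")
  descriptor_names <- descriptor_names %||% sprintf("d%d", seq_len(p))
  if (length(descriptor_names) != p) abort("`descriptor_names` must have length p.")
  structure(
    list(
      n = as.integer(n), p = as.integer(p), beta = as.numeric(beta),
      descriptor_means = as.numeric(descriptor_means),
      descriptor_sds = as.numeric(descriptor_sds),
      correlation = correlation, noise_sd = noise_sd,
      descriptor_names = descriptor_names, seed = seed
    ),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic descriptor/activity table
#'
#' Draws descriptors from the correlated Gaussian described by a
#' [synthetic_spec()] and activity from the spec's linear model plus
#' Gaussian noise. Deterministic under a fixed seed.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer RNG seed; defaults to `spec$seed`. `NULL` leaves
#'   the RNG state alone.
#' @return A tibble with columns `compound_id`, `pic50` and the spec's
#'   descriptor columns, carrying the true coefficient vector in the
#'   `beta` attribute and the spec in the `spec` attribute
#'   (see [true_beta()]).
#' @examples
#' spec <- synthetic_spec(n = 30, p = 3, beta = c(1, 2, -1, 0.5),
#'                        noise_sd = 0, seed = 7)
#' d <- generate_qsar_data(spec)
#' coef(fit_qsar(d, attr(d, "spec")$descriptor_names)) # recovers beta
#' @export
generate_qsar_data <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.null(seed)) set.seed(seed)
  C <- matrix(spec$correlation, spec$p, spec$p)
  diag(C) <- 1
  L <- tryCatch(chol(C),
                error = function(e) abort("Degenerate descriptor correlation matrix."))
  Z <- matrix(rnorm(spec$n * spec$p), spec$n, spec$p) %*% L
  X <- sweep(sweep(Z, 2, spec$descriptor_sds, "*"), 2, spec$descriptor_means, "+")
  colnames(X) <- spec$descriptor_names
  y <- spec$beta[1] + drop(X %*% spec$beta[-1]) +
    rnorm(spec$n, 0, spec$noise_sd)
  out <- dplyr::bind_cols(
    tibble(compound_id = sprintf("S%03d", seq_len(spec$n)), pic50 = y),
    as_tibble(X)
  )
  attr(out, "beta") <- setNames(spec$beta, c("(Intercept)", spec$descriptor_names))
  attr(out, "spec") <- spec
  out
}

#' True coefficients of a synthetic dataset
#'
#' @param data A tibble from [generate_qsar_data()].
#' @return Named numeric vector (intercept first).
#' @export
true_beta <- function(data) {
  b <- attr(data, "beta")
  if (is.null(b)) abort("`data` does not carry a true coefficient attribute.")
  b
}

#' Synthetic spec mimicking the bundled PTP1B training set
#'
#' A [synthetic_spec()] with the dimensions and scales of the packaged
#' 27-compound table: `n = 27`, the ten model descriptors with their
#' empirical column means and standard deviations, exchangeable
#' correlation 0.3, and the published model equation as the true
#' coefficient vector. The noise level (`noise_sd = 1.3`) was calibrated
#' once by simulation so that the expected fitted R2 of the refit is close
#' to 0.89 at these dimensions; because the synthetic descriptors lack the
#' strong structured collinearity of the real table, this spec is a
#' plausibility harness for the pipeline, not a reproduction of the real
#' data.
#'
#' @param noise_sd Override the calibrated noise level.
#' @param correlation Override the exchangeable descriptor correlation.
#' @param seed Optional seed stored in the spec.
#' @return A [synthetic_spec()].
#' @export
ptp1b_mimic_spec <- function(noise_sd = 1.3, correlation = 0.3, seed = NULL) {
  d <- ptp1b_tzd()
  desc <- ptp1b_model_descriptors()
  synthetic_spec(
    n = 27, p = length(desc),
    beta = c(-1.169, -0.683, 5.1e-3, 0.157, -0.718, -0.521, 1.038, 2.115,
             -1.41e-4, -5.446e-7, -0.441),
    descriptor_means = vapply(d[desc], mean, numeric(1)),
    descriptor_sds = vapply(d[desc], sd, numeric(1)),
    correlation = correlation, noise_sd = noise_sd,
    descriptor_names = desc, seed = seed
  )
}

#' Extract model coefficients
#'
#' @param object A [fit_qsar()] model.
#' @param ... Unused.
#' @return Named numeric vector, intercept first.
#' @export
coef.qsar_fit <- function(object, ...) object$coefficients
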