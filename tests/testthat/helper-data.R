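# Small in-code fixtures used across the suite.

# Simple-regression toy set: y = 1 + 2x exactly.
toy_linear <- function() {
  tibble::tibble(
    compound_id = paste0("c", 1:4),
    pic50 = c(1, 3, 5, 7),
    x = c(0, 1, 2, 3)
  )
}

# Random regression problem with known noise; ids r1..rn.
random_problem <- function(n, p, noise_sd = 0.5) {
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
  beta <- rnorm(p + 1)
  y <- beta[1] + drop(X %*% beta[-1]) + rnorm(n, 0, noise_sd)
  dplyr::bind_cols(
    tibble::tibble(compound_id = paste0("r", seq_len(n)), pic50 = y),
    tibble::as_tibble(X)
  )
}
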