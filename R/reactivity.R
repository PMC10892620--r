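#' Global reactivity descriptors from frontier-orbital energies
#'
#' Conceptual-DFT descriptors derived from a (HOMO, LUMO) energy pair, all
#' in eV (softness in 1/eV):
#'
#' * energy gap `eg = e_lumo - e_homo` (must be positive);
#' * chemical potential `mu = (e_lumo + e_homo)/2`;
#' * hardness `eta = (e_lumo - e_homo)/2 = eg/2`;
#' * softness `delta = 1/(2 eta)`;
#' * electrophilicity index `omega = mu^2 / (2 eta)`.
#'
#' A small gap (low hardness, high softness) marks a kinetically less
#' stable, more reactive molecule; a more negative chemical potential a
#' more stable one; a large omega a stronger electrophile.
#'
#' Inputs with `e_homo >= e_lumo` are rejected by default. Descriptor
#' tables sometimes arrive with the two orbital columns transposed (the
#' bundled training set, [ptp1b_tzd()], prints them that way);
#' `orbital_order = "swap"` swaps such pairs with a warning instead of
#' erroring.
#'
#' @param data A data frame with columns `e_homo` and `e_lumo` (eV);
#'   other columns (e.g. `compound_id`) are carried through.
#' @param orbital_order `"strict"` (default) errors when
#'   `e_homo >= e_lumo`; `"swap"` swaps offending pairs with a warning.
#' @return `data` with the columns `eg`, `eta`, `delta`, `mu`, `omega`
#'   appended (and `e_homo`/`e_lumo` corrected when swapped).
#' @examples
#' reactivity_descriptors(tzd_frontier_orbitals())
#' @export
reactivity_descriptors <- function(data, orbital_order = c("strict", "swap")) {
  orbital_order <- match.arg(orbital_order)
  if (!is.data.frame(data) || !all(c("e_homo", "e_lumo") %in% names(data))) {
    abort("`data` must be a data frame with columns `e_homo` and `e_lumo`.")
  }
  eh <- data$e_homo
  el <- data$e_lumo
  if (any(!is.finite(eh)) || any(!is.finite(el))) {
    abort("Orbital energies must be finite.")
  }
  rev_idx <- which(eh >= el)
  if (length(rev_idx) > 0) {
    if (orbital_order == "strict") {
      abort(sprintf(
        "e_homo >= e_lumo in row(s) %s; orbital energies look transposed (use orbital_order = \"swap\" to correct).",
        paste(rev_idx, collapse = ", ")
      ))
    }
    warn(sprintf("Swapping transposed orbital pair(s) in row(s): %s.",
                 paste(rev_idx, collapse = ", ")))
    tmp <- eh[rev_idx]
    eh[rev_idx] <- el[rev_idx]
    el[rev_idx] <- tmp
  }
  eg <- el - eh
  eta <- eg / 2
  mu <- (el + eh) / 2
  out <- as_tibble(data)
  out$e_homo <- eh
  out$e_lumo <- el
  out$eg <- eg
  out$eta <- eta
  out$delta <- 1 / (2 * eta)
  out$mu <- mu
  out$omega <- mu^2 / (2 * eta)
  out
}

#' Reactivity descriptors for a single orbital pair
#'
#' Scalar convenience wrapper around [reactivity_descriptors()].
#'
#' @param e_homo,e_lumo Orbital energies in eV, `e_homo < e_lumo`.
#' @return A one-row tibble with `e_homo`, `e_lumo`, `eg`, `eta`, `delta`,
#'   `mu`, `omega`.
#' @examples
#' reactivity_from_orbitals(-6.346, -2.627)$omega # ~5.412
#' @export
reactivity_from_orbitals <- function(e_homo, e_lumo) {
  stopifnot(length(e_homo) == 1, length(e_lumo) == 1)
  reactivity_descriptors(tibble(e_homo = e_homo, e_lumo = e_lumo))
}

#' Rank compounds by chemical reactivity
#'
#' Orders a batch of compounds by their energy gap: `gap_rank = 1` marks
#' the smallest gap, i.e. the most reactive (and softest) compound;
#' `softness_rank` is the descending-softness rank and, for distinct gaps,
#' the same ordering. Ties are broken lexicographically by compound id.
#' The compound with the most negative chemical potential is flagged as
#' the most stable.
#'
#' @param data A data frame as returned by [reactivity_descriptors()]
#'   (columns `compound_id`, `eg`, `delta`, `mu`).
#' @return `data` sorted from least to most reactive (descending gap),
#'   with `gap_rank` and `softness_rank` columns appended and a
#'   `most_stable` attribute holding the id of the compound with the most
#'   negative chemical potential.
#' @examples
#' rank_by_reactivity(reactivity_descriptors(tzd_frontier_orbitals()))
#' @export
rank_by_reactivity <- function(data) {
  if (!is.data.frame(data) || nrow(data) == 0 ||
      !all(c("compound_id", "eg", "delta", "mu") %in% names(data))) {
    abort("`data` must be a non-empty data frame with columns compound_id, eg, delta, mu.")
  }
  ord_gap <- order(data$eg, data$compound_id) # ascending gap = most reactive first
  gap_rank <- integer(nrow(data))
  gap_rank[ord_gap] <- seq_len(nrow(data))
  ord_soft <- order(-data$delta, data$compound_id) # descending softness
  softness_rank <- integer(nrow(data))
  softness_rank[ord_soft] <- seq_len(nrow(data))
  out <- as_tibble(data)
  out$gap_rank <- gap_rank
  out$softness_rank <- softness_rank
  out <- dplyr::arrange(out, dplyr::desc(.data$eg), .data$compound_id)
  attr(out, "most_stable") <-
    data$compound_id[order(data$mu, data$compound_id)][1]
  out
}
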