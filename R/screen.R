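#' Screen candidate compounds against a fitted model
#'
#' Predicts the activity of proposed (designed) compounds, checks each one
#' against the leverage applicability domain, and compares it to a
#' reference compound from the training series. Results are sorted by
#' predicted activity, best first, with ties broken by compound id.
#'
#' @param fit A [fit_qsar()] model.
#' @param candidates Data frame of candidate compounds carrying all model
#'   descriptor columns (an activity column is not required). A
#'   `compound_id` column is recommended; row numbers are used otherwise.
#' @param reference_id Id of a training compound to benchmark against;
#'   `NULL` skips the comparison.
#' @param compare Benchmark against the reference's `"predicted"`
#'   (default) or `"observed"` activity.
#' @param hstar_multiplier Multiplier of [warning_leverage()] (default
#'   2.5).
#' @return A tibble with columns `compound_id`, `predicted`, `leverage`,
#'   `in_domain` and (when `reference_id` is given) `exceeds_reference`,
#'   sorted by descending `predicted`. The reference activity used is
#'   stored in the `reference_activity` attribute.
#' @examples
#' fit <- fit_qsar(ptp1b_tzd(), ptp1b_model_descriptors())
#' screen_candidates(fit, ptp1b_tzd()[1:5, ], reference_id = "7e(ref)")
#' @export
screen_candidates <- function(fit, candidates, reference_id = NULL,
                              compare = c("predicted", "observed"),
                              hstar_multiplier = 2.5) {
  stopifnot(inherits(fit, "qsar_fit"))
  compare <- match.arg(compare)
  if (!is.data.frame(candidates)) abort("`candidates` must be a data frame.")
  if (nrow(candidates) == 0) {
    out <- tibble(compound_id = character(), predicted = numeric(),
                  leverage = numeric(), in_domain = logical())
    if (!is.null(reference_id)) out$exceeds_reference <- logical()
    return(out)
  }
  ids <- if (fit$id %in% names(candidates)) {
    as.character(candidates[[fit$id]])
  } else {
    sprintf("candidate_%d", seq_len(nrow(candidates)))
  }
  pred <- unname(predict(fit, candidates))
  dom <- assess_new_compounds(fit, candidates, hstar_multiplier)
  out <- tibble(
    compound_id = ids,
    predicted = pred,
    leverage = dom$leverage,
    in_domain = dom$in_domain
  )
  ref_value <- NULL
  if (!is.null(reference_id)) {
    ref_ids <- as.character(fit$data[[fit$id]])
    if (!reference_id %in% ref_ids) {
      abort(sprintf("Reference compound '%s' is not in the training set.", reference_id))
    }
    ref_value <- if (compare == "predicted") {
      unname(fit$fitted[match(reference_id, ref_ids)])
    } else {
      fit$data[[fit$activity]][match(reference_id, ref_ids)]
    }
    out$exceeds_reference <- out$predicted > ref_value
  }
  out <- dplyr::arrange(out, dplyr::desc(.data$predicted), .data$compound_id)
  attr(out, "reference_activity") <- ref_value
  out
}
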