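#' Run the full QSAR modelling and validation pipeline
#'
#' Orchestrates, in order: model fitting, the validation statistic suite
#' (including leave-one-out), Y-randomization, the leverage applicability
#' domain, and (when candidates are supplied) candidate screening. Every
#' report stamps the inputs, seed and package version, and an optional
#' output directory receives the bundle as JSON plus the Williams-plot
#' coordinates as CSV. Two runs with the same inputs and seed produce
#' byte-identical files.
#'
#' @param data Training table (data frame) or path to a CSV readable by
#'   [read_qsar_data()]. Defaults to the bundled PTP1B set.
#' @param descriptors Descriptor columns to model; defaults to
#'   [ptp1b_model_descriptors()].
#' @param activity,id Activity and identifier column names.
#' @param trials Y-randomization trial count (default 50).
#' @param seed Integer RNG seed for the scrambling trials (default 1).
#' @param hstar_multiplier,residual_band Applicability-domain settings;
#'   see [assess_domain()].
#' @param candidates Optional data frame (or CSV path) of candidate
#'   compounds to screen.
#' @param reference_id Training compound to benchmark candidates against
#'   (default the compound with the highest observed activity).
#' @param out_dir Optional directory for the report files
#'   (`qsar_report.json`, `williams.csv`).
#' @return A list of class `qsar_pipeline` with elements `fit`,
#'   `validation`, `y_randomization`, `domain`, `screening` (or `NULL`),
#'   and `meta`.
#' @examples
#' \donttest{
#' res <- run_qsar_pipeline(trials = 10, seed = 1)
#' glance(res$validation)
#' }
#' @export
run_qsar_pipeline <- function(data = NULL, descriptors = NULL,
                              activity = "pic50", id = "compound_id",
                              trials = 50, seed = 1,
                              hstar_multiplier = 2.5, residual_band = 3,
                              candidates = NULL, reference_id = NULL,
                              out_dir = NULL) {
  input_label <- "ptp1b-fixture"
  if (is.null(data)) {
    data <- ptp1b_tzd()
    descriptors <- descriptors %||% ptp1b_model_descriptors()
  } else if (is.character(data)) {
    input_label <- data
    data <- read_qsar_data(data, activity = activity, id = id)
  } else {
    input_label <- "in-memory data frame"
  }
  descriptors <- descriptors %||% setdiff(names(data), c(id, activity))
  if (is.character(candidates)) {
    candidates <- read_qsar_data(candidates, activity = activity, id = id,
                                 descriptors = descriptors)
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  fit <- stage("fit", fit_qsar(data, descriptors, activity = activity, id = id))
  validation <- stage("validate", validate_qsar(fit))
  yrand <- stage("y-randomization", y_randomization(fit, n_trials = trials, seed = seed))
  domain <- stage("applicability-domain",
                  assess_domain(fit, residual_band = residual_band,
                                hstar_multiplier = hstar_multiplier))
  screening <- NULL
  if (!is.null(candidates)) {
    if (is.null(reference_id)) {
      reference_id <- as.character(data[[id]])[which.max(data[[activity]])]
    }
    screening <- stage("screening",
                       screen_candidates(fit, candidates, reference_id = reference_id,
                                         hstar_multiplier = hstar_multiplier))
  }
  meta <- list(
    input = input_label,
    activity = activity,
    descriptors = descriptors,
    trials = trials,
    seed = seed,
    hstar_multiplier = hstar_multiplier,
    residual_band = residual_band,
    package_version = as.character(utils::packageVersion("qsarmlr"))
  )
  res <- structure(
    list(fit = fit, validation = validation, y_randomization = yrand,
         domain = domain, screening = screening, meta = meta),
    class = "qsar_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline_reports(res, out_dir)
  res
}

# Serialize the pipeline bundle to out_dir as JSON + Williams CSV.
write_pipeline_reports <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(
    meta = res$meta,
    fit = list(
      coefficients = as.list(res$fit$coefficients),
      rss = res$fit$rss,
      n = res$fit$n,
      p = res$fit$p,
      per_compound = augment(res$fit)[, c(res$fit$id, res$fit$activity)] |>
        dplyr::mutate(predicted = unname(res$fit$fitted),
                      residual = unname(res$fit$residuals),
                      leverage = unname(res$fit$hat))
    ),
    validation = glance(res$validation),
    y_randomization = list(
      summary = glance(res$y_randomization),
      trials = res$y_randomization$trials
    ),
    domain = list(
      h_star = attr(res$domain, "h_star"),
      residual_band = attr(res$domain, "residual_band"),
      per_compound = as_tibble(res$domain)
    ),
    screening = res$screening
  )
  jsonlite::write_json(report, file.path(out_dir, "qsar_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  readr::write_csv(as_tibble(res$domain), file.path(out_dir, "williams.csv"),
                   progress = FALSE)
  invisible(res)
}

#' @export
print.qsar_pipeline <- function(x, ...) {
  cat("QSAR pipeline run on", x$meta$input, "\n\n")
  print(x$fit)
  cat("\n")
  print(x$validation)
  cat("\n")
  print(x$y_randomization)
  cat(sprintf("\nApplicability domain: h* = %.3f, %d/%d compounds flagged\n",
              attr(x$domain, "h_star"),
              sum(x$domain$high_leverage | x$domain$residual_outlier),
              nrow(x$domain)))
  if (!is.null(x$screening)) {
    cat("\nTop candidates:\n")
    print(utils::head(x$screening, 5))
  }
  invisible(x)
}
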