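#' Convert IC50 (molar) to pIC50
#'
#' Activities are modelled on the negative decadic log scale,
#' `pIC50 = -log10(IC50)`, with IC50 in mol/L. Higher pIC50 means a more
#' potent inhibitor.
#'
#' @param ic50 Numeric vector of IC50 values in mol/L; must be finite and
#'   strictly positive.
#' @return Numeric vector of pIC50 values.
#' @examples
#' pic50_from_ic50(1e-5) # 5
#' pic50_from_ic50(10^(-5.337)) # 5.337
#' @export
pic50_from_ic50 <- function(ic50) {
  if (!is.numeric(ic50) || length(ic50) == 0) {
    abort("`ic50` must be a non-empty numeric vector.")
  }
  bad <- !is.finite(ic50) | ic50 <= 0
  if (any(bad)) {
    abort(sprintf(
      "IC50 values must be finite and > 0 (offending element(s): %s).",
      paste(which(bad), collapse = ", ")
    ))
  }
  -log10(ic50)
}

#' The bundled PTP1B thiazolidinedione training set
#'
#' Returns the packaged 27-compound table of 5-(substituted benzylidene)
#' thiazolidine-2,4-dione PTP1B inhibitors: observed pIC50 plus 19 molecular
#' descriptors per compound (physico-chemical, quantum-electronic, Mulliken
#' partial charges, and topological indices). The table is transcribed
#' verbatim from its published source, including two printed anomalies that
#' are deliberately left untouched: compound `7h` carries an implausibly
#' small `mw` cell (47.544), and the `e_homo`/`e_lumo` columns of the
#' training compounds are transposed (the value in `e_homo` exceeds the one
#' in `e_lumo`). Neither column enters the 10-descriptor activity model; see
#' [reactivity_descriptors()] for how the orbital-order anomaly is handled
#' when those columns are consumed.
#'
#' @return A tibble with 27 rows and 21 columns: `compound_id`, `pic50`,
#'   and the descriptors `logp`, `mw`, `logs`, `mr`, `mv`, `pol`, `e_homo`,
#'   `e_lumo`, `e_total`, `hba`, `hbd`, `q_s`, `q_n`, `q_c1`, `q_c2`,
#'   `q_c3`, `clsc`, `tindx`, `bindx`.
#' @seealso [ptp1b_model_descriptors()] for the ten predictors of the
#'   activity model, [fit_qsar()] to refit it.
#' @examples
#' d <- ptp1b_tzd()
#' d[d$compound_id == "7e(ref)", c("pic50", "logp", "mv", "clsc")]
#' @export
ptp1b_tzd <- function() {
  path <- system.file("extdata", "ptp1b_tzd.csv", package = "qsarmlr", mustWork = TRUE)
  read_qsar_data(path)
}

#' Descriptor set of the PTP1B activity model
#'
#' The ten predictors of the published pIC50 model, in equation order:
#' octanol/water partition coefficient, molar volume, molar refractivity,
#' Mulliken charges on N, S and two carbons, molecular topological index,
#' Balaban index, and cluster count.
#'
#' @return Character vector of ten descriptor names.
#' @export
ptp1b_model_descriptors <- function() {
  c("logp", "mv", "mr", "q_n", "q_s", "q_c3", "q_c2", "tindx", "bindx", "clsc")
}

#' Frontier-orbital energies of the designed PTP1B candidates
#'
#' HOMO/LUMO energies (eV, DFT B3LYP/6-311++G(d,p)) for the seven designed
#' thiazolidinedione derivatives `11a`--`11g` and the reference compound
#' `7e(ref)`, as inputs for [reactivity_descriptors()].
#'
#' @return A tibble with columns `compound_id`, `e_homo`, `e_lumo`.
#' @export
tzd_frontier_orbitals <- function() {
  tibble(
    compound_id = c("11a", "11b", "11c", "11d", "11e", "11f", "11g", "7e(ref)"),
    e_homo = c(-6.028, -8.339, -6.276, -6.265, -6.346, -6.001, -5.971, -6.149),
    e_lumo = c(-2.314, -1.273, -2.596, -2.561, -2.627, -2.375, -2.242, -2.465)
  )
}

#' Read a compound/descriptor/activity table from CSV
#'
#' Expects a header row, a compound-identifier column, one numeric activity
#' column and one numeric column per descriptor (decimal point `.`, UTF-8).
#' Parsing is strict: a missing column, a non-numeric cell, an empty file,
#' or a duplicated/empty compound id raises an error naming the offending
#' row and column.
#'
#' @param path Path to a CSV file.
#' @param activity Name of the activity column (default `"pic50"`).
#' @param id Name of the compound-identifier column (default
#'   `"compound_id"`).
#' @param descriptors Optional character vector of descriptor columns that
#'   must be present; defaults to every column other than `id` and
#'   `activity`.
#' @return A tibble with the id column as character and all other retained
#'   columns numeric, preserving row order.
#' @export
read_qsar_data <- function(path, activity = "pic50", id = "compound_id",
                           descriptors = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("Input file does not exist: '%s'.", path))
  }
  raw <- tryCatch(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE),
    error = function(e) abort(sprintf("Cannot parse '%s' as CSV: %s", path, conditionMessage(e)))
  )
  if (nrow(raw) == 0 || ncol(raw) == 0) {
    abort(sprintf("'%s' contains no data rows.", path))
  }
  for (col in c(id, activity)) {
    if (!col %in% names(raw)) {
      abort(sprintf("Required column '%s' is missing from '%s'.", col, path))
    }
  }
  descriptors <- descriptors %||% setdiff(names(raw), c(id, activity))
  missing_desc <- setdiff(descriptors, names(raw))
  if (length(missing_desc) > 0) {
    abort(sprintf("Descriptor column(s) missing from '%s': %s.",
                  path, paste(missing_desc, collapse = ", ")))
  }
  out <- raw[, c(id, activity, descriptors)]
  ids <- out[[id]]
  if (any(is.na(ids) | ids == "")) {
    abort(sprintf("Empty compound id in row(s): %s.",
                  paste(which(is.na(ids) | ids == ""), collapse = ", ")))
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    abort(sprintf("Duplicated compound id(s): %s.", paste(unique(dup), collapse = ", ")))
  }
  for (col in c(activity, descriptors)) {
    parsed <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(parsed) & !is.na(out[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("Non-numeric value '%s' in column '%s', row %d.",
                    out[[col]][bad[1]], col, bad[1]))
    }
    if (anyNA(parsed)) {
      abort(sprintf("Missing value in column '%s', row %d.", col, which(is.na(parsed))[1]))
    }
    out[[col]] <- parsed
  }
  as_tibble(out)
}

#' Write a compound table to CSV
#'
#' Inverse of [read_qsar_data()]: values written with full precision so
#' that a write/read round trip reproduces decimal inputs exactly.
#'
#' @param data A data frame of compounds.
#' @param path Output CSV path.
#' @return `data`, invisibly.
#' @export
write_qsar_data <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(data)
}

# Validate a modelling table; returns list(X, y, ids) with X the
# intercept-augmented design matrix.
check_design <- function(data, descriptors, activity, id) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  missing_cols <- setdiff(c(id, activity, descriptors), names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("Column(s) missing from `data`: %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  if (length(descriptors) == 0) abort("At least one descriptor is required.")
  ids <- as.character(data[[id]])
  if (anyDuplicated(ids)) abort("Compound ids must be unique.")
  y <- data[[activity]]
  Xd <- as.matrix(data[, descriptors, drop = FALSE])
  if (!is.numeric(y) || !is.numeric(Xd)) {
    abort("Activity and descriptor columns must be numeric.")
  }
  if (any(!is.finite(y)) || any(!is.finite(Xd))) {
    abort("Activity and descriptor values must all be finite.")
  }
  X <- cbind(`(Intercept)` = 1, Xd)
  list(X = X, y = as.numeric(y), ids = ids)
}
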