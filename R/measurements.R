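#' Validate a long-format measurement table
#'
#' Checks the structural assumptions the two-stage procedure relies on: one
#' row per measurement, every participant measured by exactly one evaluator,
#' no missing values in the outcome or in any covariate used downstream.
#'
#' @param data A data frame with one row per measurement.
#' @param outcome,evaluator,participant Names of the outcome, evaluator-id and
#'   participant-id columns.
#' @param covariate_cols Optional character vector of covariate columns to
#'   check for missingness. Defaults to every column other than the three
#'   identifier/outcome columns.
#'
#' @return The input as a tibble, invisibly ordered as given, with the three
#'   core columns verified. Errors (class `evalqc_validation_error`) name the
#'   offending column or participants.
#' @export
validate_measurements <- function(data,
                                  outcome = "outcome",
                                  evaluator = "evaluator_id",
                                  participant = "participant_id",
                                  covariate_cols = NULL) {
  data <- tibble::as_tibble(data)
  needed <- c(participant, evaluator, outcome)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    abort(paste0("Missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "evalqc_validation_error")
  }
  if (!is.numeric(data[[outcome]])) {
    abort(sprintf("Outcome column '%s' must be numeric.", outcome),
          class = "evalqc_validation_error")
  }
  covariate_cols <- covariate_cols %||% setdiff(names(data), needed)
  for (col in c(needed, covariate_cols)) {
    if (anyNA(data[[col]])) {
      abort(sprintf("Column '%s' contains missing values; rows with missing data must be resolved, not dropped silently.",
                    col),
            class = "evalqc_validation_error")
    }
  }
  # one evaluator per participant across all of that participant's rows
  per_part <- tapply(data[[evaluator]], data[[participant]],
                     function(e) length(unique(e)))
  bad <- names(per_part)[per_part > 1L]
  if (length(bad)) {
    abort(paste0("Participant(s) measured by more than one evaluator: ",
                 paste(utils::head(bad, 5L), collapse = ", "),
                 if (length(bad) > 5L) sprintf(" (and %d more)", length(bad) - 5L) else ""),
          class = "evalqc_validation_error")
  }
  invisible(data)
}

#' Read a measurement CSV
#'
#' Reads a comma-separated file with the mandatory columns `participant_id`,
#' `evaluator_id` and `outcome` (names configurable), validates it with
#' [validate_measurements()], and returns a tibble. Any remaining columns are
#' carried along as covariates; categorical covariates are expanded against a
#' reference level later, by the model formula passed to [fit_evaluators()].
#'
#' @inheritParams validate_measurements
#' @param path Path to a CSV file (comma separator, header row, `.` decimal).
#' @param factor_cols Optional named list `list(column = "reference_level")`;
#'   each listed column is converted to a factor with the given reference
#'   level first, so that model formulas expand it into indicator columns
#'   against that reference.
#'
#' @return A validated tibble of measurements.
#' @export
read_measurements <- function(path,
                              outcome = "outcome",
                              evaluator = "evaluator_id",
                              participant = "participant_id",
                              factor_cols = NULL) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in names(factor_cols %||% list())) {
    if (!col %in% names(data)) {
      abort(sprintf("factor_cols names column '%s' which is not in the file.", col),
            class = "evalqc_validation_error")
    }
    ref <- factor_cols[[col]]
    f <- factor(data[[col]])
    if (!ref %in% levels(f)) {
      abort(sprintf("Reference level '%s' not found in column '%s'.", ref, col),
            class = "evalqc_validation_error")
    }
    data[[col]] <- stats::relevel(f, ref = ref)
  }
  validate_measurements(data, outcome = outcome, evaluator = evaluator,
                        participant = participant)
  data
}
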