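#' Read a cohort metadata table
#'
#' The cohort table carries one row per (subject, vertebral level) with the
#' fracture status labels used throughout the analysis: `baseline_fractured`
#' marks a prevalent fracture already visible at the baseline scan (such
#' vertebrae are excluded from every downstream computation), and
#' `incident_fracture` marks a vertebra that was intact at baseline but
#' fractured by follow-up (the positive class of the discrimination task).
#'
#' @param path Path to a CSV file with header columns `subject_id`, `sex`,
#'   `age`, `level`, `baseline_fractured`, `incident_fracture` (extra columns
#'   are preserved).
#' @return A validated tibble.
#' @export
read_cohort <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  validate_cohort(df)
}

#' Validate a cohort table
#'
#' Checks column presence, known vertebral levels, uniqueness of
#' (subject, level), and that an incident fracture is never flagged on a
#' baseline-fractured vertebra (those are excluded from analysis before
#' incident status can be assessed).
#'
#' @param df A data frame shaped as described in [read_cohort()].
#' @return The table as a tibble, with flag columns coerced to logical.
#' @export
validate_cohort <- function(df) {
  required <- c("subject_id", "level", "baseline_fractured", "incident_fracture")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("cohort table is missing column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "vertefail_cohort_error")
  }
  df <- as_tibble(df)
  check_level(df$level)
  df$baseline_fractured <- as.logical(df$baseline_fractured)
  df$incident_fracture <- as.logical(df$incident_fracture)
  key <- paste(df$subject_id, df$level)
  if (anyDuplicated(key)) {
    abort(sprintf("duplicate (subject, level) pair(s): %s",
                  paste(unique(key[duplicated(key)]), collapse = "; ")),
          class = "vertefail_cohort_error")
  }
  if (any(df$incident_fracture & df$baseline_fractured)) {
    abort("a baseline-fractured vertebra cannot also be an incident fracture",
          class = "vertefail_cohort_error")
  }
  df
}

#' Write a result table to CSV
#'
#' @param table A data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}
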