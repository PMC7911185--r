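#' Normalization ratios of per-vertebra parameters
#'
#' Absolute failure load, failure displacement and BMD differ systematically
#' along the spine, so per-vertebra values are expressed as ratios:
#' the *global* ratio divides a vertebra's value by the subject's mean over
#' L1-L3 (the clinical reference levels), and the *local* ratio divides it
#' by the subject's mean over the vertebra's own region (T5-T12 for
#' thoracic, L1-L5 for lumbar). Both families are invariant to rescaling all
#' of a subject's values by a constant, and the local ratios of each region
#' average to exactly 1 per subject when nothing is excluded.
#'
#' Baseline-fractured vertebrae are excluded throughout: they contribute to
#' no denominator mean and receive no ratio. A vertebra that later fractures
#' (incident fracture) still contributes to the means, because its baseline
#' value predates the fracture.
#'
#' @name normalization
NULL

#' @describeIn normalization Global ratio for one subject: each level's
#'   value divided by the mean over L1-L3. Requires all of L1-L3 present and
#'   included; otherwise every ratio is `NA` with a reason.
#' @param values A data frame with columns `level`, `value` and optionally
#'   `excluded` (logical) for a single subject.
#' @return A tibble `(level, ratio)` (plus attribute `reason` if the
#'   denominator was unavailable).
#' @export
global_ratio <- function(values) {
  values <- as_tibble(values)
  excluded <- values$excluded %||% rep(FALSE, nrow(values))
  ref <- values$level %in% c("L1", "L2", "L3") & !excluded
  reason <- NULL
  if (sum(ref) < 3 || length(unique(values$level[ref])) < 3) {
    reason <- "reference levels L1-L3 incomplete or excluded"
  } else {
    denom <- mean(values$value[ref])
    if (!is.finite(denom) || denom == 0) reason <- "L1-L3 mean is zero or undefined"
  }
  out <- tibble(level = values$level,
                ratio = if (is.null(reason)) values$value / denom else NA_real_)
  out$ratio[excluded] <- NA_real_
  attr(out, "reason") <- reason
  out
}

#' @describeIn normalization Local ratio for one subject: thoracic levels
#'   divided by the included-thoracic mean, lumbar levels by the
#'   included-lumbar mean. A region needs at least 2 included vertebrae.
#' @export
local_ratio <- function(values) {
  values <- as_tibble(values)
  excluded <- values$excluded %||% rep(FALSE, nrow(values))
  region <- level_region(values$level)
  out <- tibble(level = values$level, ratio = NA_real_)
  for (r in c("thoracic", "lumbar")) {
    in_region <- region == r
    incl <- in_region & !excluded
    if (sum(incl) >= 2) {
      out$ratio[in_region] <- values$value[in_region] / mean(values$value[incl])
    }
  }
  out$ratio[excluded] <- NA_real_
  out
}

#' Full ratio table for a cohort of per-vertebra metrics
#'
#' Computes both ratio families for each parameter and subject.
#'
#' @param metrics A tibble with columns `subject_id`, `level`,
#'   `baseline_fractured`, `incident_fracture`, and the parameter columns
#'   `failure_load`, `failure_displacement`, `bmd_qct` (any subset).
#' @param parameters Named character vector mapping short parameter names to
#'   metric columns.
#' @return A long tibble: `subject_id`, `level`, `parameter`, `value`,
#'   `k_local`, `k_global`, `incident_fracture`, `excluded`.
#' @export
normalized_ratios <- function(metrics,
                              parameters = c(load = "failure_load",
                                             displacement = "failure_displacement",
                                             bmd = "bmd_qct")) {
  parameters <- parameters[unname(parameters) %in% names(metrics)]
  if (length(parameters) == 0) {
    abort("no parameter columns found in `metrics`", class = "vertefail_ratio_error")
  }
  long <- purrr::imap_dfr(parameters, function(col, pname) {
    tibble(subject_id = metrics$subject_id, level = metrics$level,
           parameter = pname, value = metrics[[col]],
           incident_fracture = metrics$incident_fracture,
           excluded = metrics$baseline_fractured)
  })
  long %>%
    group_by(.data$subject_id, .data$parameter) %>%
    dplyr::group_modify(function(df, key) {
      v <- tibble(level = df$level, value = df$value, excluded = df$excluded)
      df$k_local <- local_ratio(v)$ratio
      df$k_global <- global_ratio(v)$ratio
      df
    }) %>%
    ungroup()
}
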