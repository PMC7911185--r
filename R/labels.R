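# Fixed label scheme: thoracic levels keep their anatomical number,
# lumbar levels are offset by 20 so the two regions can never collide,
# and the calibration-phantom phases sit far outside the vertebral range.

.vertebra_labels <- c(
  T5 = 5L, T6 = 6L, T7 = 7L, T8 = 8L, T9 = 9L, T10 = 10L, T11 = 11L, T12 = 12L,
  L1 = 21L, L2 = 22L, L3 = 23L, L4 = 24L, L5 = 25L
)
.phantom_labels <- c(phantom_water = 100L, phantom_bone = 101L)

#' Vertebral level and phantom label dictionary
#'
#' The package uses a fixed integer labelling for the thoracolumbar levels
#' T5--T12 and L1--L5 plus the two calibration-phantom phases (water and
#' bone-equivalent rods).
#'
#' @param include_phantom Include the two phantom labels.
#' @return A named integer vector mapping level names to mask integers.
#' @export
#' @examples
#' label_dictionary()
label_dictionary <- function(include_phantom = TRUE) {
  if (include_phantom) c(.vertebra_labels, .phantom_labels) else .vertebra_labels
}

#' Vertebral level names in cranio-caudal order
#' @return Character vector `T5 ... T12, L1 ... L5`.
#' @export
vertebra_levels <- function() names(.vertebra_labels)

#' Spinal region of a vertebral level
#' @param level Character vector of level names (e.g. `"T7"`, `"L2"`).
#' @return `"thoracic"` or `"lumbar"` per element.
#' @export
level_region <- function(level) {
  level <- check_level(level)
  ifelse(startsWith(level, "T"), "thoracic", "lumbar")
}

check_level <- function(level) {
  bad <- setdiff(unique(level), vertebra_levels())
  if (length(bad) > 0) {
    abort(sprintf("unknown vertebral level(s): %s (supported: T5-T12, L1-L5)",
                  paste(bad, collapse = ", ")),
          class = "vertefail_level_error")
  }
  level
}

level_label <- function(level) unname(.vertebra_labels[check_level(level)])

# 1-based cranio-caudal index (T5 = 1 ... L5 = 13)
level_index <- function(level) match(check_level(level), vertebra_levels())
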