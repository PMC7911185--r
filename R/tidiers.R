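#' Tidiers and plots for pipeline result objects
#'
#' broom-style `tidy()`/`glance()` methods and ggplot2 `autoplot()` methods
#' for the load-displacement curve, ROC result and report objects.
#'
#' @param x The object.
#' @param ... Unused.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.load_displacement_curve <- function(x, ...) as_tibble(x)

#' @rdname tidiers
#' @export
glance.load_displacement_curve <- function(x, ...) {
  fp <- extract_failure(x)
  tibble(failure_load = fp$failure_load,
         failure_displacement = fp$failure_displacement,
         n_steps = nrow(x), flag = fp$flag,
         height = attr(x, "height"))
}

#' @rdname tidiers
#' @export
autoplot.load_displacement_curve <- function(x, ...) {
  fp <- extract_failure(x)
  ggplot(as_tibble(x), aes(x = .data$displacement, y = .data$reaction)) +
    geom_line() +
    geom_point(data = tibble(displacement = fp$failure_displacement,
                             reaction = fp$failure_load),
               colour = "red", size = 2) +
    labs(x = "prescribed displacement (mm)", y = "reaction force (N)",
         title = "Load-displacement curve",
         subtitle = sprintf("failure load %.0f N at %.3f mm",
                            fp$failure_load, fp$failure_displacement)) +
    theme_minimal()
}

#' @rdname tidiers
#' @export
tidy.roc_result <- function(x, ...) {
  tibble(threshold = x$thresholds, fpr = x$fpr, tpr = x$tpr)
}

#' @rdname tidiers
#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, p_value = x$p_value, ci_low = x$ci[1], ci_high = x$ci[2],
         n_pos = x$n_pos, n_neg = x$n_neg, direction = x$direction)
}

#' @rdname tidiers
#' @export
autoplot.roc_result <- function(x, ...) {
  ggplot(tidy(x), aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey") +
    geom_step() +
    labs(x = "false positive rate", y = "true positive rate",
         title = sprintf("ROC (AUC = %.3f)", x$auc)) +
    theme_minimal()
}

#' @rdname tidiers
#' @export
tidy.vertefail_report <- function(x, ...) {
  bind_rows(
    mutate(x$auc_single, combination = .data$parameter, n_parameters = 1L) %>%
      select("combination", "n_parameters", "auc", "p_value"),
    select(x$auc_combined, "combination", "n_parameters", "auc", "p_value")
  )
}

#' @rdname tidiers
#' @export
glance.vertefail_report <- function(x, ...) {
  all_auc <- tidy(x)
  best <- all_auc[which.max(all_auc$auc), ]
  tibble(n_vertebrae = x$n$n_vertebrae, n_fractured = x$n$n_fractured,
         best_combination = best$combination, best_auc = best$auc)
}

#' @rdname tidiers
#' @export
autoplot.vertefail_report <- function(x, ...) {
  ggplot(x$roc_curves, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey") +
    geom_step() +
    facet_wrap(~parameter) +
    labs(x = "false positive rate", y = "true positive rate",
         title = "Single-parameter ROC curves") +
    theme_minimal()
}
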