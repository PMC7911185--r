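#' Normality screen for analysis parameters
#'
#' One-sample Kolmogorov-Smirnov test of each parameter against a normal
#' distribution with estimated mean and sd (Lilliefors-corrected p-values).
#' Parameters failing the screen at `alpha` are flagged non-normal, which
#' motivates rank-based group comparisons downstream.
#'
#' @param df A data frame of numeric columns (one per parameter), or a long
#'   tibble with columns `parameter` and `value`.
#' @param alpha Significance level for the flag.
#' @return A tibble: `parameter`, `n`, `statistic`, `p_value`, `normal`,
#'   `testable` (`FALSE` for n < 5 or zero variance).
#' @export
normality_screen <- function(df, alpha = 0.05) {
  cols <- if (all(c("parameter", "value") %in% names(df))) {
    split(df$value, df$parameter)
  } else {
    as.list(df[vapply(df, is.numeric, logical(1))])
  }
  purrr::imap_dfr(cols, function(x, nm) {
    x <- x[is.finite(x)]
    if (length(x) < 5 || sd(x) == 0) {
      return(tibble(parameter = nm, n = length(x), statistic = NA_real_,
                    p_value = NA_real_, normal = NA, testable = FALSE))
    }
    kt <- nortest::lillie.test(x)
    tibble(parameter = nm, n = length(x), statistic = unname(kt$statistic),
           p_value = kt$p.value, normal = kt$p.value > alpha, testable = TRUE)
  })
}

#' Mann-Whitney U test
#'
#' Rank-based two-sample test. The reported `U` follows the min-rank
#' convention (the smaller of the two complementary U statistics, as
#' clinical statistics packages print it); `U1` is the number of (x, y)
#' pairs with x ranked above y, counting ties one half. The two-sided
#' p-value is computed by exact permutation enumeration for small samples
#' (combined n at most `exact_max`) and otherwise by the tie-corrected
#' normal approximation.
#'
#' @param x,y Numeric samples (both nonempty).
#' @param exact_max Largest combined sample size for exact enumeration.
#' @return A list: `U`, `U1`, `U2`, `p_value`, `method`.
#' @export
mann_whitney <- function(x, y, exact_max = 16) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) {
    abort("both groups must be nonempty", class = "vertefail_stats_error")
  }
  u1_of <- function(xx, yy) {
    r <- rank(c(xx, yy))
    sum(r[seq_along(xx)]) - length(xx) * (length(xx) + 1) / 2
  }
  U1 <- u1_of(x, y)
  U2 <- n1 * n2 - U1
  mu <- n1 * n2 / 2
  if (n1 + n2 <= exact_max) {
    pooled <- c(x, y)
    picks <- combn(n1 + n2, n1)
    dev_obs <- abs(U1 - mu) - 1e-9
    devs <- apply(picks, 2, function(ii) {
      abs(u1_of(pooled[ii], pooled[-ii]) - mu)
    })
    p <- mean(devs >= dev_obs)
    method <- "exact enumeration"
  } else {
    N <- n1 + n2
    ties <- table(c(x, y))
    v <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (U1 - mu) / sqrt(v)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation (tie-corrected)"
  }
  list(U = min(U1, U2), U1 = U1, U2 = U2, p_value = min(p, 1), method = method)
}

#' ROC curve and AUC for a single score
#'
#' Builds the empirical ROC curve and integrates it by the trapezoid rule.
#' The AUC is verified against the rank (Mann-Whitney) identity
#' `AUC = U1 / (n1 * n2)` with ties counted one half -- the two must agree
#' to numerical precision, and the function asserts that they do. The
#' p-value against AUC = 0.5 uses the tie-corrected Mann-Whitney normal
#' approximation, and the confidence interval is Hanley-McNeil.
#'
#' @param scores Numeric score per observation.
#' @param labels Logical (or 0/1): `TRUE` marks the positive class
#'   (fractured).
#' @param direction `"higher"` if larger scores indicate the positive class,
#'   `"lower"` for the opposite, `"auto"` to orient by the sign of the group
#'   mean difference (the chosen orientation is recorded in the result).
#' @param conf_level Confidence level of the AUC interval.
#' @return A `roc_result` list: `auc`, `p_value`, `ci`, `fpr`, `tpr`,
#'   `thresholds`, `n_pos`, `n_neg`, `direction`.
#' @export
roc_auc <- function(scores, labels, direction = c("auto", "higher", "lower"),
                    conf_level = 0.95) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    abort("both classes must be present", class = "vertefail_stats_error")
  }
  if (direction == "auto") {
    direction <- if (mean(scores[labels]) >= mean(scores[!labels])) "higher" else "lower"
  }
  s <- if (direction == "higher") scores else -scores

  thr <- sort(unique(s), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(s[labels] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(s[!labels] >= t), numeric(1))
  fpr <- c(0, fpr); tpr <- c(0, tpr)
  auc_trap <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)

  mw <- mann_whitney(s[labels], s[!labels], exact_max = 0)  # force U machinery
  auc_u <- mw$U1 / (n_pos * n_neg)
  if (abs(auc_trap - auc_u) > 1e-10) {
    abort("internal inconsistency: trapezoid AUC != U/(n1*n2)",
          class = "vertefail_stats_error")
  }

  q1 <- auc_u / (2 - auc_u)
  q2 <- 2 * auc_u^2 / (1 + auc_u)
  se <- sqrt((auc_u * (1 - auc_u) + (n_pos - 1) * (q1 - auc_u^2) +
                (n_neg - 1) * (q2 - auc_u^2)) / (n_pos * n_neg))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- c(max(0, auc_u - zq * se), min(1, auc_u + zq * se))

  structure(list(auc = auc_u, p_value = mw$p_value, ci = ci, se = se,
                 fpr = fpr, tpr = tpr, thresholds = c(Inf, thr),
                 n_pos = n_pos, n_neg = n_neg, direction = direction),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f (95%% CI %.3f-%.3f), p = %.4g, %d pos / %d neg, direction: %s\n",
              x$auc, x$ci[1], x$ci[2], x$p_value, x$n_pos, x$n_neg, x$direction))
  invisible(x)
}

#' Combine parameters into a single discriminative score
#'
#' Fits an in-sample binary logistic model on the chosen ratio columns and
#' uses its linear predictor as the combined score, then computes the ROC.
#' No cross-validation is performed (apparent AUCs). Under perfect
#' separation the fit falls back to a lightly ridge-penalized logistic
#' model and the result is flagged.
#'
#' @param df Data frame holding the columns and labels.
#' @param columns Character vector (length >= 1) of score columns.
#' @param labels Logical vector or name of a logical column in `df`.
#' @return A list: `roc` (a `roc_result`), `coefficients`, `n_used`,
#'   `separation` (logical flag), `columns`.
#' @export
combine_parameters <- function(df, columns, labels = "incident_fracture") {
  lab <- if (is.character(labels) && length(labels) == 1) df[[labels]] else labels
  X <- as.data.frame(df[, columns, drop = FALSE])
  cc <- complete.cases(X) & !is.na(lab)
  X <- X[cc, , drop = FALSE]
  y <- as.logical(lab[cc])
  fit_df <- cbind(X, .y = y)
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = fit_df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  if (separation || !fit$converged || any(abs(coef(fit)[-1]) > 1e3, na.rm = TRUE)) {
    separation <- TRUE
    beta <- ridge_logistic(as.matrix(X), y)
    score <- as.numeric(cbind(1, as.matrix(X)) %*% beta)
    coefs <- setNames(as.numeric(beta), c("(Intercept)", columns))
  } else {
    score <- as.numeric(predict(fit, type = "link"))
    coefs <- coef(fit)
  }
  list(roc = roc_auc(score, y, direction = "higher"),
       coefficients = coefs, n_used = sum(cc), separation = separation,
       columns = columns)
}

# small ridge-penalized logistic regression by IRLS (intercept unpenalized)
ridge_logistic <- function(X, y, lambda = 0.05, max_iter = 100, tol = 1e-8) {
  Xs <- scale(X)
  ctr <- attr(Xs, "scaled:center"); scl <- attr(Xs, "scaled:scale")
  scl[scl == 0] <- 1
  Xs <- cbind(1, sweep(sweep(X, 2, ctr), 2, scl, "/"))
  p <- ncol(Xs)
  pen <- diag(c(0, rep(lambda, p - 1)))
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(Xs %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- pmax(mu * (1 - mu), 1e-8)
    z <- eta + (y - mu) / W
    beta_new <- solve(crossprod(Xs, Xs * W) + pen, crossprod(Xs, W * z))
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  # un-standardize
  b <- as.numeric(beta)
  slopes <- b[-1] / scl
  c(b[1] - sum(slopes * ctr), slopes)
}

#' Healthy-vs-fractured comparison and discrimination report
#'
#' Produces the full statistical report for a ratio table: descriptive
#' group statistics (mean +/- sd for healthy and fractured vertebrae) with
#' Mann-Whitney p-values for every parameter in both normalization
#' families, single-parameter ROC/AUC including the reference-standard
#' L1-L3 mean BMD, and AUCs for the standard parameter combinations (all
#' pairs and the triple of local ratios, plus the combined global ratios).
#'
#' Load and BMD ratios are oriented lower-score-positive and the
#' displacement ratio higher-score-positive by the `"auto"` direction rule;
#' the orientation used is recorded per row. The statistical unit is the
#' vertebra.
#'
#' @param ratios A [normalized_ratios()] table.
#' @param bmd_table Per-vertebra BMD table (to derive the reference
#'   standard), e.g. [cohort_bmd()] output with `subject_id`, `level`,
#'   `bmd_qct`, `excluded`.
#' @return A `vertefail_report` list: `group_stats`, `auc_single`,
#'   `auc_combined`, `roc_curves`, `normality`, `n`.
#' @export
run_report <- function(ratios, bmd_table = NULL) {
  used <- filter(ratios, !.data$excluded)

  wide <- used %>%
    tidyr::pivot_wider(id_cols = c("subject_id", "level", "incident_fracture"),
                       names_from = "parameter",
                       values_from = c("k_local", "k_global"))

  if (!is.null(bmd_table)) {
    std <- purrr::map_dfr(split(bmd_table, bmd_table$subject_id), function(d) {
      ref <- bmd_standard(tibble(level = d$level, bmd_qct = d$bmd_qct,
                                 baseline_fractured = d$excluded))
      tibble(subject_id = d$subject_id[1], bmd_standard = ref$bmd_standard)
    })
    wide <- left_join(wide, std, by = "subject_id")
  }

  params <- setdiff(names(wide), c("subject_id", "level", "incident_fracture"))
  lab <- wide$incident_fracture

  group_stats <- purrr::map_dfr(params, function(pn) {
    v <- wide[[pn]]
    h <- v[!lab & is.finite(v)]
    f <- v[lab & is.finite(v)]
    mw <- if (length(h) > 0 && length(f) > 0) mann_whitney(h, f) else
      list(U = NA_real_, p_value = NA_real_)
    tibble(parameter = pn,
           healthy_mean = mean(h), healthy_sd = sd(h),
           fractured_mean = mean(f), fractured_sd = sd(f),
           U = mw$U, p_value = mw$p_value,
           n_healthy = length(h), n_fractured = length(f))
  })

  roc_one <- function(pn) {
    v <- wide[[pn]]
    keep <- is.finite(v)
    roc_auc(v[keep], lab[keep], direction = "auto")
  }
  rocs <- setNames(lapply(params, roc_one), params)
  auc_single <- purrr::imap_dfr(rocs, function(r, pn) {
    tibble(parameter = pn, auc = r$auc, p_value = r$p_value,
           ci_low = r$ci[1], ci_high = r$ci[2], direction = r$direction)
  })

  local_cols <- intersect(c("k_local_load", "k_local_displacement", "k_local_bmd"),
                          params)
  combos <- list()
  if (length(local_cols) >= 2) {
    pairs <- combn(local_cols, 2, simplify = FALSE)
    combos <- c(combos, pairs)
  }
  if (length(local_cols) == 3) combos <- c(combos, list(local_cols))
  global_cols <- intersect(c("k_global_load", "k_global_displacement",
                             "k_global_bmd"), params)
  if (length(global_cols) >= 2) combos <- c(combos, list(global_cols))

  combined <- purrr::map(combos, function(cols) {
    combine_parameters(wide, cols, labels = lab)
  })
  auc_combined <- purrr::map_dfr(combined, function(cmb) {
    tibble(combination = paste(cmb$columns, collapse = " + "),
           n_parameters = length(cmb$columns),
           auc = cmb$roc$auc, p_value = cmb$roc$p_value,
           separation = cmb$separation)
  })

  roc_curves <- purrr::imap_dfr(rocs, function(r, pn) {
    tibble(parameter = pn, fpr = r$fpr, tpr = r$tpr)
  })

  long_vals <- used %>%
    select("parameter", value = "k_local") %>%
    mutate(parameter = paste0("k_local_", .data$parameter))

  structure(list(
    group_stats = group_stats,
    auc_single = auc_single,
    auc_combined = auc_combined,
    roc_curves = roc_curves,
    normality = normality_screen(long_vals),
    rocs = rocs,
    combined = combined,
    n = tibble(n_vertebrae = nrow(wide), n_fractured = sum(lab),
               n_healthy = sum(!lab))
  ), class = "vertefail_report")
}

#' @export
print.vertefail_report <- function(x, ...) {
  cat(sprintf("<vertefail_report> %d vertebrae (%d fractured, %d healthy)\n",
              x$n$n_vertebrae, x$n$n_fractured, x$n$n_healthy))
  cat("\nSingle-parameter AUCs:\n")
  print(as.data.frame(x$auc_single), digits = 3)
  if (nrow(x$auc_combined) > 0) {
    cat("\nCombined-parameter AUCs:\n")
    print(as.data.frame(x$auc_combined), digits = 3)
  }
  invisible(x)
}
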