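test_that("the normality screen flags distributions correctly", {
  set.seed(19)
  df <- tibble::tibble(gaussian = rnorm(500), skewed = rlnorm(500, 0, 1))
  out <- normality_screen(df)
  expect_true(out$normal[out$parameter == "gaussian"])
  expect_false(out$normal[out$parameter == "skewed"])

  const <- normality_screen(tibble::tibble(flat = rep(1, 50)))
  expect_false(const$testable)
  tiny <- normality_screen(tibble::tibble(x = c(1, 2, 3)))
  expect_false(tiny$testable)
})

test_that("Mann-Whitney U follows the min-rank convention with exact small-n p", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p_value, 0.1)  # 2 / choose(6, 3)
  expect_match(mw$method, "exact")

  # order swap leaves U and p unchanged
  mw_swap <- mann_whitney(c(4, 5, 6), c(1, 2, 3))
  expect_equal(mw_swap$U, mw$U)
  expect_equal(mw_swap$p_value, mw$p_value)

  # identical groups: p in the null region
  same <- mann_whitney(c(2, 2, 3, 4), c(2, 2, 3, 4))
  expect_gt(same$p_value, 0.9)
})

test_that("Mann-Whitney agrees with the reference implementation", {
  set.seed(5)
  for (i in 1:10) {
    x <- round(rnorm(4 + i %% 3, 0, 4), 2)
    y <- round(rnorm(5, 1, 4), 2)
    mine <- mann_whitney(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE, correct = FALSE))
    expect_equal(mine$U1, unname(ref$statistic))
    if (!any(duplicated(c(x, y)))) {
      expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    }
  }
  # large-sample branch vs normal-approximation reference
  set.seed(6)
  x <- rnorm(40); y <- rnorm(35, 0.5)
  mine <- mann_whitney(x, y)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  expect_match(mine$method, "normal")
})

test_that("trapezoid AUC equals the pair-counting oracle and the U identity", {
  set.seed(23)
  for (i in 1:50) {
    n <- sample(20:60, 1)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.3, 0.7))
    if (sum(labels) == 0 || sum(!labels) == 0) labels[1:2] <- c(TRUE, FALSE)
    scores <- round(rnorm(n, mean = labels), 1)  # rounding induces ties
    r <- roc_auc(scores, labels, direction = "higher")
    expect_equal(r$auc, oracle_pair_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("ROC handles separation, direction and the null case", {
  lab <- c(rep(FALSE, 10), rep(TRUE, 10))
  r <- roc_auc(c(rnorm(10, 0), rnorm(10, 100)), lab, direction = "higher")
  expect_equal(r$auc, 1)
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[length(r$tpr)], 1)
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))

  # lower-score-positive orientation mirrors the score axis
  r_low <- roc_auc(c(rnorm(10, 100), rnorm(10, 0)), lab, direction = "lower")
  expect_equal(r_low$auc, 1)

  set.seed(77)
  null_r <- roc_auc(rnorm(200), sample(c(TRUE, FALSE), 200, replace = TRUE),
                    direction = "higher")
  expect_lt(abs(null_r$auc - 0.5), 0.1)
  expect_gt(null_r$p_value, 0.01)
})

test_that("combining parameters never hurts and degenerates gracefully", {
  set.seed(41)
  n <- 150
  lab <- runif(n) < 0.3
  df <- tibble::tibble(
    informative = rnorm(n, mean = ifelse(lab, 1, 0)),
    noise = rnorm(n),
    incident_fracture = lab
  )
  single <- roc_auc(df$informative, lab, direction = "higher")
  self_combo <- combine_parameters(df, c("informative"))
  expect_equal(self_combo$roc$auc, single$auc, tolerance = 1e-12)

  # the in-sample logistic score maximizes likelihood, not AUC, so adding a
  # pure-noise column can move the apparent AUC by a hair in either direction
  with_noise <- combine_parameters(df, c("informative", "noise"))
  expect_gte(with_noise$roc$auc, single$auc - 0.01)

  # perfectly separable input falls back to the ridge fit, flagged
  sep <- tibble::tibble(x = c(rnorm(20, -5), rnorm(20, 5)),
                        incident_fracture = rep(c(FALSE, TRUE), each = 20))
  cs <- combine_parameters(sep, "x")
  expect_true(cs$separation)
  expect_equal(cs$roc$auc, 1)
})

test_that("the report has the documented layout including the BMD standard", {
  set.seed(12)
  metrics <- tidyr::expand_grid(subject_id = sprintf("S%d", 1:6),
                                level = vertebra_levels()) %>%
    dplyr::mutate(
      baseline_fractured = FALSE,
      incident_fracture = runif(dplyr::n()) < 0.15,
      failure_load = runif(dplyr::n(), 1000, 4000),
      failure_displacement = runif(dplyr::n(), 0.1, 0.5),
      bmd_qct = runif(dplyr::n(), 40, 120)
    )
  ratios <- normalized_ratios(metrics)
  bmd_tab <- dplyr::select(metrics, subject_id, level, bmd_qct,
                           excluded = baseline_fractured)
  rep1 <- run_report(ratios, bmd_tab)
  rep2 <- run_report(ratios, bmd_tab)
  expect_equal(rep1$auc_single, rep2$auc_single)  # deterministic

  expect_setequal(names(rep1$group_stats),
                  c("parameter", "healthy_mean", "healthy_sd", "fractured_mean",
                    "fractured_sd", "U", "p_value", "n_healthy", "n_fractured"))
  expect_true("bmd_standard" %in% rep1$auc_single$parameter)
  expect_true(all(c("k_local_load", "k_global_load") %in%
                    rep1$group_stats$parameter))
  trip <- "k_local_load + k_local_displacement + k_local_bmd"
  expect_true(trip %in% rep1$auc_combined$combination)
  expect_true(all(rep1$auc_single$auc >= 0 & rep1$auc_single$auc <= 1))
  # tidiers
  td <- tidy(rep1)
  expect_true(all(c("combination", "auc") %in% names(td)))
  expect_s3_class(glance(rep1), "tbl_df")
})
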