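test_that("noiseless construction hits the trabecular target exactly", {
  v <- make_vertebra_volume("T8", trabecular_hu = 150, noise_sd = 0)
  roi <- place_roi(v$volume, v$mask, "T8")
  expect_equal(roi$mean_hu, 150)
  expect_gte(roi$n_voxels, 25)
})

test_that("lumbar bodies are larger and carry more mineral than thoracic", {
  t5 <- make_vertebra_volume("T5", trabecular_hu = 150, noise_sd = 0)
  l5 <- make_vertebra_volume("L5", trabecular_hu = 150, noise_sd = 0)
  mineral <- function(v, lev) {
    sum(v$volume$voxels[v$mask$labels == vertefail:::level_label(lev)])
  }
  expect_gt(mineral(l5, "L5"), mineral(t5, "T5"))
  expect_gt(sum(l5$mask$labels == 25L), sum(t5$mask$labels == 5L))
})

test_that("vertebra generation is bit-identical under a fixed seed", {
  a <- make_vertebra_volume("L2", 120, noise_sd = 8, seed = 42)
  b <- make_vertebra_volume("L2", 120, noise_sd = 8, seed = 42)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$mask$labels, b$mask$labels)
})

test_that("each vertebral label forms one nonempty connected component", {
  v <- make_vertebra_volume("T12", 130, noise_sd = 0)
  lab <- v$mask$labels == 12L
  expect_gt(sum(lab), 0)
  idx <- which(lab, arr.ind = TRUE)
  keep <- vertefail:::largest_component(idx[, 1], idx[, 2], idx[, 3])
  expect_true(all(keep))  # single component
})

test_that("the exact incident pattern yields 23 fractures (11x1 + 3x2 + 2x3)", {
  sim_tab <- withr::with_seed(7, {
    params <- cohort_sim_params(n_subjects = 16, seed = 7, incident_mode = "exact")
    # counts only; no volumes needed for this check
    simulate_cohort(params)$cohort
  })
  expect_equal(sum(sim_tab$incident_fracture), 23)
  per_subject <- table(tapply(sim_tab$incident_fracture, sim_tab$subject_id, sum))
  expect_equal(unname(per_subject[c("1", "2", "3")]), c(11L, 3L, 2L),
               ignore_attr = TRUE)
  expect_false(any(sim_tab$incident_fracture & sim_tab$baseline_fractured))
})

test_that("cohort simulation is deterministic and recovers the BMD targets", {
  params <- cohort_sim_params(n_subjects = 4, seed = 3, incident_mode = "sampled",
                              baseline_rate = 0)
  sim1 <- simulate_cohort(params)
  sim2 <- simulate_cohort(params)
  expect_identical(sim1$cohort, sim2$cohort)
  expect_identical(sim1$volumes[[5]]$volume$voxels, sim2$volumes[[5]]$volume$voxels)

  bmd <- cohort_bmd(sim1)
  joined <- dplyr::left_join(bmd, sim1$cohort, by = c("subject_id", "level"))
  # ROI means recover the generator's per-vertebra targets despite HU noise
  expect_lt(max(abs(joined$bmd_qct - joined$true_bmd_qct)), 10)
  # regional means within 2 regional sd of the configured targets
  thor <- joined$bmd_qct[level_region(joined$level) == "thoracic" &
                           !joined$incident_fracture]
  lumb <- joined$bmd_qct[level_region(joined$level) == "lumbar" &
                           !joined$incident_fracture]
  expect_lt(abs(mean(thor) - 80.47), 2 * 17.56)
  expect_lt(abs(mean(lumb) - 69.77), 2 * 17.01)
})

test_that("a larger HU deficit widens the healthy-fractured BMD ratio gap", {
  gap <- function(deficit) {
    sim <- simulate_cohort(cohort_sim_params(
      n_subjects = 6, seed = 21, incident_mode = "sampled",
      fracture_deficit = deficit, baseline_rate = 0))
    met <- dplyr::left_join(cohort_bmd(sim), sim$cohort,
                            by = c("subject_id", "level"))
    met$baseline_fractured <- FALSE
    ratios <- normalized_ratios(met, parameters = c(bmd = "bmd_qct"))
    mean(ratios$k_local[!ratios$incident_fracture]) -
      mean(ratios$k_local[ratios$incident_fracture])
  }
  expect_gt(gap(0.75), gap(0.95))
  expect_gt(gap(0.75), 0)
})

test_that("parameter validation rejects out-of-range settings", {
  expect_error(cohort_sim_params(fracture_deficit = 0), class = "vertefail_param_error")
  expect_error(cohort_sim_params(fracture_deficit = 1.2), class = "vertefail_param_error")
  expect_error(cohort_sim_params(baseline_rate = 2), class = "vertefail_param_error")
  expect_error(cohort_sim_params(hu_water = 100, hu_bone = 50),
               class = "vertefail_param_error")
  expect_error(cohort_sim_params(n_subjects = 8, incident_mode = "exact"),
               class = "vertefail_param_error")
})
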