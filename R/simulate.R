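#' Simulation parameters for a synthetic CT vertebra cohort
#'
#' The generator emulates the statistical structure a vertebra-specific
#' fracture-prediction analysis assumes: a thoracic-vs-lumbar gradient in
#' trabecular BMD, vertebral body size increasing cranio-caudally, per-level
#' BMD variability, a two-phase calibration phantom in every volume,
#' baseline-fracture exclusions, and incident fractures at 1-3 levels in a
#' subset of subjects. To-be-fractured vertebrae receive a multiplicative
#' deficit on their local HU before image synthesis, so the fracture signal
#' propagates to BMD and to the finite-element results through the same
#' image pathway a real analysis would use.
#'
#' @param n_subjects Number of subjects (default 16).
#' @param seed Integer seed; the cohort is bit-reproducible given
#'   (params, seed).
#' @param thoracic_bmd,lumbar_bmd Named `c(mean, sd)` of the trabecular BMD
#'   target in mg/mL (QCT scale) for thoracic and lumbar levels. Defaults
#'   80.47 +/- 17.56 and 69.77 +/- 17.01 mg/mL.
#' @param bmd_floor Truncation floor for per-vertebra BMD draws (mg/mL).
#' @param fracture_deficit Multiplicative HU deficit in (0, 1] applied to
#'   to-be-fractured vertebrae (default 0.85); 1 means no effect (null
#'   cohort).
#' @param incident_mode `"exact"` reproduces the reference fracture pattern
#'   (11 subjects with one incident fracture, 3 with two, 2 with three, at
#'   the recorded levels; requires `n_subjects = 16`), `"sampled"` draws
#'   per-subject fracture counts and sites from the empirical distribution,
#'   `"none"` generates no incident fractures.
#' @param baseline_rate Per-vertebra probability of a prevalent
#'   (baseline) fracture, which excludes the vertebra from analysis.
#' @param noise_sd Gaussian HU noise standard deviation.
#' @param hu_water,hu_bone Ground-truth mean HU of the water and
#'   bone-equivalent phantom rods (parameters, so calibration code cannot
#'   assume an identity mapping).
#' @param spacing Isotropic voxel spacing in mm (default 1 mm).
#' @return A `cohort_sim_params` list.
#' @export
cohort_sim_params <- function(n_subjects = 16,
                              seed = 1,
                              thoracic_bmd = c(mean = 80.47, sd = 17.56),
                              lumbar_bmd = c(mean = 69.77, sd = 17.01),
                              bmd_floor = 5,
                              fracture_deficit = 0.85,
                              incident_mode = c("exact", "sampled", "none"),
                              baseline_rate = 0.02,
                              noise_sd = 10,
                              hu_water = 0,
                              hu_bone = 200,
                              spacing = 1) {
  incident_mode <- match.arg(incident_mode)
  if (fracture_deficit <= 0 || fracture_deficit > 1) {
    abort("fracture_deficit must be in (0, 1]", class = "vertefail_param_error")
  }
  if (any(c(thoracic_bmd["sd"], lumbar_bmd["sd"], noise_sd) < 0)) {
    abort("standard deviations must be nonnegative", class = "vertefail_param_error")
  }
  if (baseline_rate < 0 || baseline_rate > 1) {
    abort("baseline_rate must be in [0, 1]", class = "vertefail_param_error")
  }
  if (hu_bone <= hu_water) {
    abort("phantom ground truth requires hu_bone > hu_water",
          class = "vertefail_param_error")
  }
  if (incident_mode == "exact" && n_subjects != 16) {
    abort("incident_mode = 'exact' requires n_subjects = 16",
          class = "vertefail_param_error")
  }
  structure(list(
    n_subjects = n_subjects, seed = seed,
    thoracic_bmd = thoracic_bmd, lumbar_bmd = lumbar_bmd, bmd_floor = bmd_floor,
    fracture_deficit = fracture_deficit, incident_mode = incident_mode,
    baseline_rate = baseline_rate, noise_sd = noise_sd,
    hu_water = hu_water, hu_bone = hu_bone, spacing = spacing
  ), class = "cohort_sim_params")
}

# Reference incident-fracture pattern: 11 subjects with one fracture,
# 3 with two, 2 with three, at these levels.
.incident_pattern <- list(
  "T7", "T8", "T9", "T11", "T12", "T12", "L1", "L1", "L2", "L3", "L5",
  c("T5", "T12"), c("L1", "L2"), c("T5", "T9"),
  c("T12", "L1", "L2"), c("T10", "T11", "T12")
)

#' Desk-scale vertebral body geometry per level
#'
#' Simplified axis-aligned geometry: an elliptic-cylindrical vertebral body
#' with a denser shell (cortical rim and endplates modelled as denser
#' trabecular bone), plus a rectangular posterior-element block fused to the
#' posterior shell. Dimensions increase linearly from T5 to L5, mirroring
#' the cranio-caudal growth of vertebral cross-section and height, at a
#' reduced desk scale.
#'
#' @param level Vertebral level name.
#' @return A one-row tibble of geometry parameters in mm: body half-width
#'   `a`, half-depth `b`, height `h`, shell thickness, posterior block
#'   width/depth/height.
#' @export
vertebra_geometry <- function(level) {
  i <- level_index(level)  # 1 (T5) ... 13 (L5)
  a <- 9 + 4 * (i - 1) / 12
  b <- 0.78 * a
  h <- 13 + 6 * (i - 1) / 12
  tibble(
    level = level, a = a, b = b, h = h,
    shell = 1.5,
    post_w = 0.9 * a, post_d = 0.55 * b, post_h = 0.7 * h
  )
}

#' Generate one synthetic vertebra CT volume with its label mask
#'
#' Builds a CT-like sub-volume containing a single vertebra (elliptic body
#' with denser shell and endplates plus a posterior block), soft-tissue
#' background at ~40 HU, and two calibration-phantom rods (water and
#' bone-equivalent) posterior to the vertebra. With `noise_sd = 0` the
#' trabecular core mean HU equals `trabecular_hu` exactly.
#'
#' @param level Vertebral level name (drives the geometry).
#' @param trabecular_hu Target mean HU of the trabecular core.
#' @param shell_hu,posterior_hu HU of the shell/endplates and of the
#'   posterior block (defaults: core + 250 and core + 150).
#' @param noise_sd Gaussian HU noise sd added voxelwise.
#' @param hu_water,hu_bone Phantom rod mean HU.
#' @param spacing Isotropic voxel spacing (mm).
#' @param seed Optional integer seed for the noise (bitwise reproducible).
#' @return A list with elements `volume` ([ct_volume()]) and `mask`
#'   ([label_mask()]).
#' @export
make_vertebra_volume <- function(level, trabecular_hu,
                                 shell_hu = trabecular_hu + 250,
                                 posterior_hu = trabecular_hu + 150,
                                 noise_sd = 10,
                                 hu_water = 0, hu_bone = 200,
                                 spacing = 1, seed = NULL) {
  geo <- vertebra_geometry(level)
  if (geo$a <= 0 || geo$b <= 0 || geo$h <= 0) {
    abort("degenerate vertebra geometry", class = "vertefail_param_error")
  }
  rod_r <- 4
  rod_y <- geo$b + geo$post_d + 8
  # grid extents (mm), body centered at (0, 0, h/2 + 2)
  x_half <- geo$a + 6
  y_min <- -(geo$b + 5)
  y_max <- rod_y + rod_r + 3
  z_max <- geo$h + 4
  xs <- seq(-x_half, x_half, by = spacing)
  ys <- seq(y_min, y_max, by = spacing)
  zs <- seq(0, z_max, by = spacing)
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  zc <- z_max / 2

  in_z_body <- abs(zs - zc) <= geo$h / 2
  in_z_post <- abs(zs - zc) <= geo$post_h / 2
  # endplate layers: within shell thickness of the body's top/bottom
  in_z_plate <- in_z_body & (abs(zs - zc) > geo$h / 2 - geo$shell)

  ell <- function(a, b) outer(xs^2 / a^2, ys^2 / b^2, "+") <= 1  # nx x ny
  outer_xy <- ell(geo$a, geo$b)
  inner_xy <- ell(geo$a - geo$shell, geo$b - geo$shell)
  post_xy <- outer(abs(xs) <= geo$post_w / 2,
                   ys >= geo$b - 1 & ys <= geo$b + geo$post_d, "&")
  rod_w_xy <- outer((xs + 8)^2, (ys - rod_y)^2, "+") <= rod_r^2
  rod_b_xy <- outer((xs - 8)^2, (ys - rod_y)^2, "+") <= rod_r^2

  expand_z <- function(xy, zmask) {
    arr <- array(FALSE, c(nx, ny, nz))
    arr[, , zmask] <- xy
    arr
  }
  body <- expand_z(outer_xy, in_z_body)
  core <- expand_z(inner_xy, in_z_body) & !expand_z(inner_xy, in_z_plate)
  post <- expand_z(post_xy, in_z_post)
  rod_w <- expand_z(rod_w_xy, rep(TRUE, nz))
  rod_b <- expand_z(rod_b_xy, rep(TRUE, nz))

  vox <- array(40, c(nx, ny, nz))  # soft-tissue background
  vox[rod_w] <- hu_water
  vox[rod_b] <- hu_bone
  vox[post] <- posterior_hu
  vox[body] <- shell_hu
  vox[core] <- trabecular_hu

  lab <- array(0L, c(nx, ny, nz))
  lab[rod_w] <- .phantom_labels[["phantom_water"]]
  lab[rod_b] <- .phantom_labels[["phantom_bone"]]
  lab[post & !rod_w & !rod_b] <- level_label(level)
  lab[body] <- level_label(level)

  add_noise <- function() {
    if (noise_sd > 0) vox + array(rnorm(length(vox), 0, noise_sd), dim(vox)) else vox
  }
  vox <- if (is.null(seed)) add_noise() else withr::with_seed(seed, add_noise())

  origin <- c(xs[1], ys[1], zs[1])
  list(volume = ct_volume(vox, spacing = rep(spacing, 3), origin = origin),
       mask = label_mask(lab, spacing = rep(spacing, 3), origin = origin))
}

#' Simulate a full synthetic cohort
#'
#' Draws per-vertebra trabecular BMD targets from the regional
#' distributions (truncated below at `bmd_floor`), assigns incident
#' fractures per `incident_mode`, applies the multiplicative HU deficit to
#' to-be-fractured vertebrae, draws prevalent baseline fractures, and
#' synthesizes one CT volume + mask per vertebra. Ground-truth per-vertebra
#' targets are stored in the cohort table for recovery tests.
#'
#' @param params A [cohort_sim_params()] object.
#' @return A list with `volumes` (named list, one `list(volume, mask)` per
#'   subject-vertebra, names `"<subject>_<level>"`), `cohort` (tibble with
#'   labels and ground truth) and `params`.
#' @export
simulate_cohort <- function(params = cohort_sim_params()) {
  stopifnot(inherits(params, "cohort_sim_params"))
  withr::with_seed(params$seed, simulate_cohort_impl(params))
}

simulate_cohort_impl <- function(params) {
  levels <- vertebra_levels()
  n <- params$n_subjects
  subjects <- sprintf("S%02d", seq_len(n))
  sex <- sample(rep(c("m", "f"), length.out = n))
  age <- round(rnorm(n, 65, 9))

  # incident fracture sites per subject
  sites <- switch(params$incident_mode,
    none = replicate(n, character(0), simplify = FALSE),
    exact = sample(.incident_pattern),
    sampled = {
      counts <- sample(c(1L, 2L, 3L, 0L), n, replace = TRUE,
                       prob = c(11, 3, 2, 0.0001) / 16.0001)
      site_tab <- table(factor(unlist(.incident_pattern), levels = levels))
      w <- as.numeric(site_tab) + 0.25
      lapply(counts, function(k) sample(levels, k, prob = w))
    }
  )

  cohort <- tidyr::expand_grid(subject_id = subjects, level = levels) %>%
    mutate(
      sex = sex[match(.data$subject_id, subjects)],
      age = age[match(.data$subject_id, subjects)],
      region = level_region(.data$level)
    )
  cohort$incident_fracture <- purrr::map2_lgl(
    cohort$subject_id, cohort$level,
    function(s, l) l %in% sites[[match(s, subjects)]]
  )
  cohort$baseline_fractured <- !cohort$incident_fracture &
    runif(nrow(cohort)) < params$baseline_rate

  reg <- function(region, field) {
    ifelse(region == "thoracic", params$thoracic_bmd[[field]],
           params$lumbar_bmd[[field]])
  }
  base_bmd <- pmax(rnorm(nrow(cohort), reg(cohort$region, "mean"),
                         reg(cohort$region, "sd")),
                   params$bmd_floor)
  # BMD target (QCT mg/mL) -> trabecular HU via the inverse calibration map
  base_hu <- params$hu_water +
    ((base_bmd + 11) / 0.69) * (params$hu_bone - params$hu_water) / 200
  deficit <- ifelse(cohort$incident_fracture, params$fracture_deficit, 1)
  cohort$true_trabecular_hu <- deficit * base_hu
  cohort$true_bmd_mdct <- 200 * (cohort$true_trabecular_hu - params$hu_water) /
    (params$hu_bone - params$hu_water)
  cohort$true_bmd_qct <- 0.69 * cohort$true_bmd_mdct - 11

  volumes <- vector("list", nrow(cohort))
  names(volumes) <- paste(cohort$subject_id, cohort$level, sep = "_")
  for (i in seq_len(nrow(cohort))) {
    d <- deficit[i]
    volumes[[i]] <- make_vertebra_volume(
      level = cohort$level[i],
      trabecular_hu = cohort$true_trabecular_hu[i],
      shell_hu = d * (base_hu[i] + 250),
      posterior_hu = d * (base_hu[i] + 150),
      noise_sd = params$noise_sd,
      hu_water = params$hu_water, hu_bone = params$hu_bone,
      spacing = params$spacing
    )
  }
  list(volumes = volumes,
       cohort = select(cohort, "subject_id", "sex", "age", "level",
                       "baseline_fractured", "incident_fracture",
                       "true_trabecular_hu", "true_bmd_mdct", "true_bmd_qct"),
       params = params)
}
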