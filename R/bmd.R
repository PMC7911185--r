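#' Phantom calibration from the in-scan reference phantom
#'
#' Estimates the mean HU of the water and bone-equivalent phantom rods from
#' their mask labels. The rods correspond to 0 and 200 mg/mL hydroxyapatite.
#'
#' @param volume A [ct_volume()].
#' @param mask A congruent [label_mask()] containing both phantom labels.
#' @return A `phantom_calibration` list with `hu_water`, `hu_bone`,
#'   `ha_water = 0`, `ha_bone = 200` (mg/mL).
#' @export
calibrate <- function(volume, mask) {
  check_congruent(volume, mask)
  wl <- .phantom_labels[["phantom_water"]]
  bl <- .phantom_labels[["phantom_bone"]]
  w_idx <- mask$labels == wl
  b_idx <- mask$labels == bl
  if (!any(w_idx) || !any(b_idx)) {
    abort("calibration requires both phantom labels (water and bone rods)",
          class = "vertefail_calibration_error")
  }
  hu_w <- mean(volume$voxels[w_idx])
  hu_b <- mean(volume$voxels[b_idx])
  if (hu_b <= hu_w) {
    abort("phantom bone rod must be denser than water rod (HU_b > HU_w)",
          class = "vertefail_calibration_error")
  }
  structure(list(hu_water = hu_w, hu_bone = hu_b, ha_water = 0, ha_bone = 200),
            class = "phantom_calibration")
}

#' @export
print.phantom_calibration <- function(x, ...) {
  cat(sprintf("<phantom_calibration> HU_w = %.2f, HU_b = %.2f (0 / 200 mg/mL HA)\n",
              x$hu_water, x$hu_bone))
  invisible(x)
}

#' Trabecular ROI mean HU on the central slice of a vertebral body
#'
#' Automatically places an elliptical region of interest in the trabecular
#' compartment of the anterior vertebral body: the most central axial slice
#' of the level is selected, the body cross-section is identified from its
#' row-width profile (the posterior-element block is narrower than 60% of
#' the maximal body width and is discarded), and an ellipse with half-axes
#' 40% of the estimated body half-width/half-depth is centered in the
#' anterior half, equidistant from both endplates. The slice is eroded by
#' `margin` voxels from the label boundary, which removes the thin cortical
#' shell, so only trabecular voxels contribute. Placement is deterministic.
#'
#' @param volume A [ct_volume()].
#' @param mask Congruent [label_mask()].
#' @param level Vertebral level name.
#' @param margin Erosion margin in voxels from the label boundary.
#' @param axes_frac ROI half-axes as a fraction of the body half-axes.
#' @param anterior_frac Anterior offset of the ROI center as a fraction of
#'   the body half-depth.
#' @param min_voxels Minimum admissible ROI size.
#' @return A `vertefail_roi` list: `mean_hu`, `n_voxels`, `slice`, `center`
#'   (voxel indices), `half_axes` (voxels).
#' @export
place_roi <- function(volume, mask, level, margin = 2, axes_frac = 0.4,
                      anterior_frac = 0.25, min_voxels = 25) {
  check_congruent(volume, mask)
  lab <- level_label(level)
  hit <- mask$labels == lab
  if (!any(hit)) {
    abort(sprintf("level %s not present in mask", level),
          class = "vertefail_roi_error")
  }
  zs <- which(apply(hit, 3, any))
  z_mid <- zs[ceiling(length(zs) / 2)]
  M <- hit[, , z_mid]

  widths <- colSums(M)  # in-slice x-width per y row
  wmax <- max(widths)
  body_rows <- which(widths >= 0.6 * wmax)
  # ellipse-chord correction: rows wider than 60% of the max span |y| <=
  # b*sqrt(1 - 0.6^2) = 0.8 b, so rescale the detected half-extent
  b_est <- (diff(range(body_rows)) / 2 + 0.5) / 0.8
  y_c <- mean(range(body_rows))
  a_est <- wmax / 2
  x_in_body <- which(apply(M[, body_rows, drop = FALSE], 1, any))
  x_c <- mean(range(x_in_body))

  eroded <- erode_slice(M, margin)
  # anterior is -y by the package axis convention
  yc_roi <- y_c - anterior_frac * b_est
  ax <- axes_frac * a_est
  ay <- axes_frac * b_est
  xi <- seq_len(nrow(M)); yi <- seq_len(ncol(M))
  in_roi <- outer((xi - x_c)^2 / ax^2, (yi - yc_roi)^2 / ay^2, "+") <= 1
  roi <- in_roi & eroded
  n_vox <- sum(roi)
  if (n_vox < min_voxels) {
    abort(sprintf("ROI too small (%d < %d voxels) for level %s",
                  n_vox, min_voxels, level),
          class = "vertefail_roi_error")
  }
  structure(list(
    mean_hu = mean(volume$voxels[, , z_mid][roi]),
    n_voxels = n_vox, slice = z_mid,
    center = c(x_c, yc_roi), half_axes = c(ax, ay)
  ), class = "vertefail_roi")
}

# binary erosion of a 2D slice by a (2m+1)^2 square structuring element
erode_slice <- function(M, margin) {
  if (margin <= 0) return(M)
  pad <- function(A) {
    out <- matrix(FALSE, nrow(A) + 2, ncol(A) + 2)
    out[2:(nrow(A) + 1), 2:(ncol(A) + 1)] <- A
    out
  }
  E <- M
  for (k in seq_len(margin)) {
    P <- pad(E)
    i <- 2:(nrow(P) - 1); j <- 2:(ncol(P) - 1)
    E <- P[i, j] & P[i - 1, j] & P[i + 1, j] & P[i, j - 1] & P[i, j + 1] &
      P[i - 1, j - 1] & P[i - 1, j + 1] & P[i + 1, j - 1] & P[i + 1, j + 1]
  }
  E
}

#' BMD from HU via the two-point phantom calibration
#'
#' Linear map anchored at the phantom phases:
#' `BMD_MDCT = HA_b / (HU_b - HU_w) * (HU - HU_w)` (mg/mL), exact at both
#' anchors and invariant to adding a constant to all HU values.
#'
#' @param hu HU value(s).
#' @param calibration A [calibrate()] result.
#' @return BMD_MDCT in mg/mL.
#' @export
bmd_mdct <- function(hu, calibration) {
  stopifnot(inherits(calibration, "phantom_calibration"))
  calibration$ha_bone / (calibration$hu_bone - calibration$hu_water) *
    (hu - calibration$hu_water)
}

#' Convert scanner-specific BMD to QCT-equivalent BMD
#'
#' Affine cross-calibration `BMD_QCT = 0.69 * BMD_MDCT - 11` mg/mL. Negative
#' outputs are possible for very low HU and propagate unchanged (clamping
#' would bias the downstream ratio statistics).
#'
#' @param bmd BMD_MDCT in mg/mL.
#' @return BMD_QCT in mg/mL.
#' @export
mdct_to_qct <- function(bmd) 0.69 * bmd - 11

#' Reference-standard BMD: mean of L1-L3
#'
#' The clinical reference standard is the mean QCT BMD over L1, L2 and L3.
#' If any of the three is missing or baseline-fractured the standard is
#' reported missing with a reason code rather than computed from a subset.
#'
#' @param records A data frame with columns `level`, `bmd_qct` and
#'   `baseline_fractured` for one subject.
#' @return A list with `bmd_standard` (mg/mL or `NA`) and `reason`
#'   (`"ok"`, `"missing_level"` or `"baseline_fractured"`).
#' @export
bmd_standard <- function(records) {
  need <- c("L1", "L2", "L3")
  rows <- records[records$level %in% need, , drop = FALSE]
  if (length(unique(rows$level)) < 3 || any(is.na(rows$bmd_qct))) {
    return(list(bmd_standard = NA_real_, reason = "missing_level"))
  }
  if (any(rows$baseline_fractured)) {
    return(list(bmd_standard = NA_real_, reason = "baseline_fractured"))
  }
  list(bmd_standard = mean(rows$bmd_qct), reason = "ok")
}

#' Per-vertebra BMD table for a simulated cohort
#'
#' Runs phantom calibration and ROI placement on every vertebra volume and
#' returns the BMD record table (scanner and QCT scales).
#'
#' @param sim A [simulate_cohort()] result.
#' @return A tibble: `subject_id`, `level`, `roi_mean_hu`, `n_roi_voxels`,
#'   `bmd_mdct`, `bmd_qct`, `excluded` (baseline fracture flag).
#' @export
cohort_bmd <- function(sim) {
  purrr::pmap_dfr(
    list(sim$cohort$subject_id, sim$cohort$level, sim$cohort$baseline_fractured),
    function(s, l, excl) {
      v <- sim$volumes[[paste(s, l, sep = "_")]]
      cal <- calibrate(v$volume, v$mask)
      roi <- place_roi(v$volume, v$mask, l)
      mdct <- bmd_mdct(roi$mean_hu, cal)
      tibble(subject_id = s, level = l, roi_mean_hu = roi$mean_hu,
             n_roi_voxels = roi$n_voxels, bmd_mdct = mdct,
             bmd_qct = mdct_to_qct(mdct), excluded = excl)
    }
  )
}
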