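#' CT volume container
#'
#' A minimal container for a 3D grid of Hounsfield units (HU) with voxel
#' spacing and world origin. The axis convention is fixed: axis order is
#' (x, y, z) with z the cranio-caudal (axial) direction, +y pointing
#' posterior, voxel indices 0-based, and world position = origin +
#' index * spacing (voxel centers).
#'
#' @param voxels 3D numeric array of HU values.
#' @param spacing Numeric length-3, voxel spacing in mm (all > 0).
#' @param origin Numeric length-3, world offset in mm of voxel (0,0,0).
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3) {
    abort("`voxels` must be a 3D array", class = "vertefail_volume_error")
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be 3 strictly positive numbers (mm)",
          class = "vertefail_volume_error")
  }
  if (length(origin) != 3 || any(!is.finite(origin))) {
    abort("`origin` must be 3 finite numbers (mm)", class = "vertefail_volume_error")
  }
  if (any(!is.finite(voxels))) {
    abort("HU values must all be finite", class = "vertefail_volume_error")
  }
  if (max(abs(voxels)) > 10000) {
    abort("implausible HU values (|HU| > 10000); refusing volume",
          class = "vertefail_volume_error")
  }
  structure(
    list(voxels = voxels, spacing = spacing, origin = origin, axes = "xyz/z-axial"),
    class = "ct_volume"
  )
}

#' Integer label mask congruent with a CT volume grid
#'
#' @param labels 3D integer array (0 = background) on the same grid as its
#'   companion [ct_volume()].
#' @param spacing,origin Grid geometry, as in [ct_volume()].
#' @param dictionary Named integer vector mapping names to label values;
#'   defaults to [label_dictionary()].
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       dictionary = label_dictionary()) {
  if (!is.array(labels) || length(dim(labels)) != 3) {
    abort("`labels` must be a 3D array", class = "vertefail_mask_error")
  }
  if (any(labels != round(labels))) {
    abort("labels must be integers", class = "vertefail_mask_error")
  }
  storage.mode(labels) <- "integer"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0)) {
    abort("`spacing` must be 3 strictly positive numbers (mm)",
          class = "vertefail_mask_error")
  }
  structure(
    list(labels = labels, spacing = spacing, origin = as.numeric(origin),
         dictionary = dictionary, axes = "xyz/z-axial"),
    class = "label_mask"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s voxels, spacing %s mm, HU range [%.1f, %.1f]\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.label_mask <- function(x, ...) {
  present <- sort(setdiff(unique(as.vector(x$labels)), 0L))
  nm <- names(x$dictionary)[match(present, x$dictionary)]
  cat(sprintf("<label_mask> %s voxels, labels: %s\n",
              paste(dim(x$labels), collapse = "x"),
              paste(ifelse(is.na(nm), present, nm), collapse = ", ")))
  invisible(x)
}

#' Check that a volume and a mask share the same grid
#'
#' Shape must match exactly and spacing to 1e-6 mm; anything else is a
#' congruence error.
#'
#' @param volume A [ct_volume()].
#' @param mask A [label_mask()].
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
check_congruent <- function(volume, mask) {
  stopifnot(inherits(volume, "ct_volume"), inherits(mask, "label_mask"))
  if (!identical(dim(volume$voxels), dim(mask$labels))) {
    abort("volume and mask shapes differ", class = "vertefail_congruence_error")
  }
  if (max(abs(volume$spacing - mask$spacing)) > 1e-6) {
    abort("volume and mask spacing differ by more than 1e-6 mm",
          class = "vertefail_congruence_error")
  }
  invisible(TRUE)
}

# world coordinate of voxel centers along one axis (0-based indices)
axis_coords <- function(n, spacing, origin) origin + (seq_len(n) - 1) * spacing
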