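# Binary 3D morphology with axis-aligned box structuring elements.
#
# A box element is separable, so erosion (dilation) is the sequential 1D
# windowed AND (OR) along each axis. Voxels outside the volume count as
# background, the usual convention for brain masks well inside the field
# of view.

# Shift a 3D logical array by `by` voxels along `axis`, filling with FALSE.
.axis_shift <- function(x, axis, by) {
  d <- dim(x)
  perm <- c(axis, setdiff(seq_along(d), axis))
  xp <- aperm(x, perm)
  dp <- dim(xp)
  m <- matrix(xp, nrow = dp[1])
  out <- matrix(FALSE, nrow = dp[1], ncol = ncol(m))
  src <- seq_len(dp[1]) - by
  ok <- src >= 1 & src <= dp[1]
  out[ok, ] <- m[src[ok], ]
  dim(out) <- dp
  aperm(out, order(perm))
}

# Separable box morphology; radii_vox is the per-axis half-width in voxels.
.box_morph <- function(mask, radii_vox, op = c("erode", "dilate")) {
  op <- match.arg(op)
  out <- mask
  for (a in 1:3) {
    r <- radii_vox[a]
    if (r == 0) next
    acc <- out
    for (o in seq_len(r)) {
      if (op == "erode") {
        acc <- acc & .axis_shift(out, a, o) & .axis_shift(out, a, -o)
      } else {
        acc <- acc | .axis_shift(out, a, o) | .axis_shift(out, a, -o)
      }
    }
    out <- acc
  }
  out
}

# mm -> voxel half-width: ceil guarantees at least the stated physical margin
.mm_to_vox <- function(mm, spacing) as.integer(ceiling(mm / spacing - 1e-9))

#' Erode a binary mask by a physical margin
#'
#' Morphological erosion with an axis-aligned box element whose half-width
#' per axis is `ceiling(radius_mm / spacing_axis)` voxels, guaranteeing at
#' least the stated physical margin in every direction. Used to erode
#' subcortical grey matter and normal-appearing white matter masks (by
#' 1 mm in all directions, by default elsewhere in the pipeline) to reduce
#' partial volume artefact.
#'
#' @param mask Binary 3D array (logical or 0/1).
#' @param radius_mm Erosion margin in mm; 0 returns the mask unchanged.
#' @param spacing Voxel spacing, mm, length-3 vector.
#'
#' @return A logical 3D array; may be empty.
#' @export
erode_isotropic <- function(mask, radius_mm, spacing) {
  m <- as_binary_array(mask)
  assert_scalar_pos(radius_mm, "radius_mm", strict = FALSE)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop_invalid("`spacing` must be 3 positive values (mm)")
  }
  if (radius_mm == 0) return(m)
  .box_morph(m, .mm_to_vox(radius_mm, spacing), "erode")
}

#' Dilate a mask by a physical margin (box element)
#'
#' Companion to [erode_isotropic()]; mainly useful for opening/closing
#' checks and for building exclusion margins.
#'
#' @inheritParams erode_isotropic
#' @return A logical 3D array; always a superset of the input.
#' @export
dilate_isotropic <- function(mask, radius_mm, spacing) {
  m <- as_binary_array(mask)
  assert_scalar_pos(radius_mm, "radius_mm", strict = FALSE)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop_invalid("`spacing` must be 3 positive values (mm)")
  }
  if (radius_mm == 0) return(m)
  .box_morph(m, .mm_to_vox(radius_mm, spacing), "dilate")
}

# Resolve which array axis runs left-right, anterior-posterior,
# superior-inferior from an orientation string such as "RAS" or "LPI"
# (character i = anatomical direction of increasing array index i).
.axes_from_orientation <- function(orientation) {
  ax <- toupper(strsplit(orientation, "")[[1]])
  if (length(ax) != 3L) return(NULL)
  lab <- character(3)
  lab[ax %in% c("L", "R")] <- "LR"
  lab[ax %in% c("A", "P")] <- "AP"
  lab[ax %in% c("S", "I")] <- "SI"
  if (!setequal(lab, c("LR", "AP", "SI"))) return(NULL)
  lab
}

#' Dilate a ventricle mask anisotropically
#'
#' Dilates with a box element sized per anatomical axis: by `lr_mm` to the
#' left and right and by `ap_mm` / `si_mm` along the anterior-posterior and
#' superior-inferior axes. The dilated ventricle mask is subtracted from
#' white-matter masks to exclude tissue contaminated by the large vessels
#' running along the ventricles.
#'
#' @param ventricle_mask Binary 3D array (logical or 0/1).
#' @param spacing Voxel spacing, mm, length-3 vector.
#' @param lr_mm,ap_mm,si_mm Dilation extents per anatomical axis, mm; 0
#'   extents give the identity.
#' @param axes Character length-3 giving the anatomical axis of each array
#'   dimension, a permutation of `c("LR","AP","SI")`. If `NULL`, taken
#'   from the mask's `axes` attribute (set e.g. by
#'   [simulate_phantom_masks()] or from NIfTI orientation metadata);
#'   missing metadata is an error.
#'
#' @return A logical 3D array, a superset of the input.
#' @export
dilate_ventricles_anisotropic <- function(ventricle_mask, spacing,
                                          lr_mm = 5, ap_mm = 4, si_mm = 4,
                                          axes = NULL) {
  m <- as_binary_array(ventricle_mask, "ventricle_mask")
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop_invalid("`spacing` must be 3 positive values (mm)")
  }
  assert_scalar_pos(lr_mm, "lr_mm", strict = FALSE)
  assert_scalar_pos(ap_mm, "ap_mm", strict = FALSE)
  assert_scalar_pos(si_mm, "si_mm", strict = FALSE)
  if (is.null(axes)) axes <- attr(ventricle_mask, "axes")
  if (is.character(axes) && length(axes) == 1L) {
    axes <- .axes_from_orientation(axes)
  }
  if (is.null(axes) || !setequal(axes, c("LR", "AP", "SI"))) {
    stop(errorCondition(
      "anatomical axis mapping unavailable: supply `axes` or orientation metadata",
      class = c("cvrsvd_orientation_error", "error")))
  }
  mm <- c(LR = lr_mm, AP = ap_mm, SI = si_mm)[axes]
  r <- integer(3)
  for (a in 1:3) r[a] <- if (mm[a] == 0) 0L else .mm_to_vox(mm[a], spacing[a])
  if (all(r == 0)) return(m)
  .box_morph(m, r, "dilate")
}

#' Subtract one mask from another
#'
#' `target AND NOT exclusion`, on identical grids.
#'
#' @param target,exclusion Binary 3D arrays on the same grid.
#' @return A logical 3D array.
#' @export
subtract_mask <- function(target, exclusion) {
  t_ <- as_binary_array(target, "target")
  e_ <- as_binary_array(exclusion, "exclusion")
  if (!identical(dim(t_), dim(e_))) {
    stop(errorCondition("target and exclusion masks are on different grids",
                        class = c("cvrsvd_grid_error", "error")))
  }
  t_ & !e_
}
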