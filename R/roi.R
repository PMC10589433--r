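#' Bundle tissue masks on a common grid
#'
#' @param masks Named list of binary 3D arrays on one grid. Recognised
#'   labels: `sgm`, `nawm`, `wmh`, `ventricles`, `large_vessel_exclusion`
#'   (optional); other labels are carried through untouched.
#' @param spacing_mm Voxel spacing, mm, length-3.
#' @param axes Anatomical axis of each array dimension, permutation of
#'   `c("LR","AP","SI")`; needed for anisotropic ventricle dilation.
#' @param provenance Character vector of morphology steps already applied.
#'
#' @return An `roi_mask_set` object.
#' @export
roi_mask_set <- function(masks, spacing_mm, axes = c("LR", "AP", "SI"),
                         provenance = character()) {
  if (!is.list(masks) || is.null(names(masks)) || any(names(masks) == "")) {
    stop_invalid("`masks` must be a named list")
  }
  masks <- lapply(masks, as_binary_array)
  dims <- lapply(masks, dim)
  if (length(unique(dims)) != 1L) {
    stop(errorCondition("all masks must share one grid",
                        class = c("cvrsvd_grid_error", "error")))
  }
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0)) {
    stop_invalid("`spacing_mm` must be 3 positive values")
  }
  structure(list(masks = masks, spacing_mm = as.numeric(spacing_mm),
                 axes = axes, provenance = provenance),
            class = "roi_mask_set")
}

#' @export
print.roi_mask_set <- function(x, ...) {
  d <- dim(x$masks[[1]])
  cat(sprintf("ROI mask set on a %dx%dx%d grid (%.3g x %.3g x %.3g mm):\n",
              d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]))
  for (nm in names(x$masks)) {
    cat(sprintf("  %-24s %d voxels\n", nm, sum(x$masks[[nm]])))
  }
  if (length(x$provenance)) {
    cat("Provenance:\n")
    cat(paste0("  - ", x$provenance, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Condition tissue masks for CVR extraction
#'
#' Applies the mask-conditioning sequence used before ROI extraction, in
#' order: (1) erode the subcortical grey matter and normal-appearing white
#' matter masks by `erode_mm` in all directions (partial-volume
#' reduction); (2) dilate the ventricle mask anisotropically (default 5 mm
#' left-right, 4 mm anterior-posterior and superior-inferior) to cover the
#' large vessels running along the ventricles; (3) subtract the dilated
#' ventricle mask from the NAWM and WMH masks; (4) if present, subtract
#' the large-vessel exclusion mask from all tissue masks. WMH masks are
#' not eroded. Each step is appended to the set's provenance.
#'
#' @param mask_set An [roi_mask_set()] with labels `sgm`, `nawm`, `wmh`,
#'   `ventricles` (and optionally `large_vessel_exclusion`).
#' @param erode_mm Isotropic erosion margin for SGM and NAWM, mm.
#' @param ventricle_lr_mm,ventricle_ap_mm,ventricle_si_mm Ventricle
#'   dilation extents, mm.
#'
#' @return The conditioned `roi_mask_set`.
#' @export
prepare_roi_masks <- function(mask_set, erode_mm = 1,
                              ventricle_lr_mm = 5, ventricle_ap_mm = 4,
                              ventricle_si_mm = 4) {
  stopifnot(inherits(mask_set, "roi_mask_set"))
  need <- c("sgm", "nawm", "wmh", "ventricles")
  missing_lab <- setdiff(need, names(mask_set$masks))
  if (length(missing_lab)) {
    stop_invalid("mask set lacks labels: ", paste(missing_lab, collapse = ", "))
  }
  sp <- mask_set$spacing_mm
  out <- mask_set

  out$masks$sgm <- erode_isotropic(out$masks$sgm, erode_mm, sp)
  out$masks$nawm <- erode_isotropic(out$masks$nawm, erode_mm, sp)
  out$provenance <- c(out$provenance,
                      sprintf("eroded sgm, nawm by %g mm (box element)", erode_mm))

  vent_dil <- dilate_ventricles_anisotropic(out$masks$ventricles, sp,
                                            lr_mm = ventricle_lr_mm,
                                            ap_mm = ventricle_ap_mm,
                                            si_mm = ventricle_si_mm,
                                            axes = out$axes)
  out$provenance <- c(out$provenance,
                      sprintf("dilated ventricles by %g mm LR, %g mm AP, %g mm SI",
                              ventricle_lr_mm, ventricle_ap_mm, ventricle_si_mm))

  out$masks$nawm <- subtract_mask(out$masks$nawm, vent_dil)
  out$masks$wmh <- subtract_mask(out$masks$wmh, vent_dil)
  out$provenance <- c(out$provenance,
                      "subtracted dilated ventricle mask from nawm, wmh")

  if (!is.null(out$masks$large_vessel_exclusion)) {
    for (lab in c("sgm", "nawm", "wmh")) {
      out$masks[[lab]] <- subtract_mask(out$masks[[lab]],
                                        out$masks$large_vessel_exclusion)
    }
    out$provenance <- c(out$provenance,
                        "subtracted large-vessel exclusion mask from sgm, nawm, wmh")
  }
  out
}

#' Extract the mean BOLD time series of an ROI
#'
#' Arithmetic mean over mask voxels, per volume. The number of voxels is
#' recorded; an empty mask is an error (as happens when a small WMH mask
#' empties after registration and conditioning).
#'
#' @param bold_4d 4D numeric array (x, y, z, volume).
#' @param mask Binary 3D array matching the spatial grid.
#' @param label ROI label stored in the result.
#'
#' @return An `roi_series` object: list with `label`, `mean_signal`
#'   (length = number of volumes) and `n_voxels`.
#' @export
extract_roi_mean_series <- function(bold_4d, mask, label = "roi") {
  if (length(dim(bold_4d)) != 4L) stop_invalid("`bold_4d` must be a 4D array")
  m <- as_binary_array(mask)
  if (!identical(dim(bold_4d)[1:3], dim(m))) {
    stop(errorCondition("mask grid does not match the BOLD spatial grid",
                        class = c("cvrsvd_grid_error", "error")))
  }
  idx <- which(m)
  if (!length(idx)) {
    stop(errorCondition(sprintf("ROI '%s' is empty", label),
                        class = c("cvrsvd_empty_roi", "error")))
  }
  nt <- dim(bold_4d)[4]
  flat <- matrix(bold_4d, nrow = prod(dim(m)), ncol = nt)
  structure(
    list(label = label, mean_signal = colMeans(flat[idx, , drop = FALSE]),
         n_voxels = length(idx)),
    class = "roi_series"
  )
}
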