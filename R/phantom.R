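#' Simulate phantom tissue masks
#'
#' Builds a deterministic digital head phantom hosting all the structures
#' the mask-conditioning pipeline operates on: an ellipsoidal brain, a
#' central ventricle slab, two subcortical grey matter (SGM) blobs, a
#' normal-appearing white matter (NAWM) shell and white matter
#' hyperintensity (WMH) caps face-adjacent to the ventricles (so the
#' ventricle-dilation subtraction is always exercised). All structure
#' masks are pairwise disjoint. The seed jitters the SGM blob centres by
#' up to one voxel; a fixed seed gives bit-identical masks.
#'
#' @param shape Grid size, length-3 integer, each >= 16.
#' @param spacing_mm Voxel spacing, mm, length-3 (default 2.5 mm
#'   isotropic, the BOLD resolution).
#' @param seed RNG seed recorded in the output.
#'
#' @return An [roi_mask_set()] with masks `sgm`, `nawm`, `wmh`,
#'   `ventricles`, `brain`, axes `c("LR","AP","SI")` and the seed as
#'   attribute.
#' @export
simulate_phantom_masks <- function(shape = c(32, 32, 32),
                                   spacing_mm = c(2.5, 2.5, 2.5),
                                   seed = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 16L)) {
    stop_invalid("`shape` must be 3 integers, each >= 16, to host all structures")
  }
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0)) {
    stop_invalid("`spacing_mm` must be 3 positive values")
  }

  d1 <- shape[1]; d2 <- shape[2]; d3 <- shape[3]
  X <- array(rep(seq_len(d1), times = d2 * d3), shape)
  Y <- array(rep(rep(seq_len(d2), each = d1), times = d3), shape)
  Z <- array(rep(seq_len(d3), each = d1 * d2), shape)
  ctr <- (shape + 1) / 2

  ellipsoid <- function(c0, r) {
    ((X - c0[1]) / r[1])^2 + ((Y - c0[2]) / r[2])^2 + ((Z - c0[3]) / r[3])^2 <= 1
  }
  box <- function(c0, h) {
    abs(X - c0[1]) <= h[1] & abs(Y - c0[2]) <= h[2] & abs(Z - c0[3]) <= h[3]
  }

  brain <- ellipsoid(ctr, 0.45 * shape)

  vh <- c(max(1, round(d1 / 16)), max(2, round(d2 / 10)), max(1, round(d3 / 16)))
  vent <- box(ctr, vh)

  # WMH caps: boxes stacked against the ventricle ends along Y (face
  # adjacency under 26- and even 6-connectivity); deep enough that part
  # of each cap survives the ventricle-dilation subtraction at BOLD
  # resolution
  wy <- max(4, round(d2 / 8))
  y_hi <- floor(ctr[2] + vh[2]) + 1 + (wy - 1) / 2   # centre of upper cap
  y_lo <- ceiling(ctr[2] - vh[2]) - 1 - (wy - 1) / 2
  hw <- c(vh[1], (wy - 1) / 2 + 0.4, vh[3])
  wmh <- (box(c(ctr[1], y_hi, ctr[3]), hw) |
          box(c(ctr[1], y_lo, ctr[3]), hw)) & brain & !vent

  jit <- with_seed(seed, sample(-1:1, 6, replace = TRUE))
  rs <- max(2, round(d1 / 9))
  off <- vh[1] + rs + 2
  sgm <- ellipsoid(ctr + c(off + jit[1], jit[2], jit[3]), rep(rs, 3)) |
         ellipsoid(ctr - c(off + jit[4], jit[5], jit[6]), rep(rs, 3))
  sgm <- sgm & brain & !vent & !wmh

  occupied <- vent | wmh | sgm
  buffer <- .box_morph(occupied, c(1L, 1L, 1L), "dilate")
  nawm <- ellipsoid(ctr, 0.38 * shape) & !buffer

  masks <- list(sgm = sgm, nawm = nawm, wmh = wmh, ventricles = vent,
                brain = brain)
  if (any(!vapply(masks[c("sgm", "nawm", "wmh", "ventricles")], any, logical(1)))) {
    stop_invalid("`shape` too small to host all phantom structures")
  }

  out <- roi_mask_set(masks, spacing_mm, axes = c("LR", "AP", "SI"),
                      provenance = "simulated phantom")
  attr(out, "seed") <- seed
  out
}
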