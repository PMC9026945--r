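#' Region-growing parameters
#'
#' Collects the tunable parameters of the plaque-extraction stage.
#'
#' @param window_radius Half-width in voxels of the cubic search window used
#'   for seed correction and the initial threshold; the default 3 gives the
#'   7 x 7 x 7 window.
#' @param sigma Gaussian smoothing width in voxel units applied per axis
#'   before region growing (default 0.5); `0` disables smoothing.
#' @param connectivity Voxel neighbourhood: 6 (faces), 18 (faces + edges) or
#'   26 (full cube, default).
#' @param threshold_step Positive decrement applied to the growing threshold
#'   between passes, in native intensity units (default 1).
#' @param doubling_factor Growth ratio beyond which a pass is treated as a
#'   flood into surrounding tissue (default 2: region "more than doubled").
#' @param doubling_min_voxels Minimum region size before the doubling stop may
#'   fire (default 100, about 18 mm^3 at the default spacing). Early growth
#'   away from the seed routinely doubles a small region from one pass to the
#'   next — that is legitimate accretion, not flooding — so the guard is armed
#'   only once the region has reached a plaque-like size.
#' @param threshold_floor Lowest threshold considered; defaults to the
#'   minimum of the smoothed volume, which guarantees termination.
#' @return A list of class `region_grow_params`.
#' @export
region_grow_params <- function(window_radius = 3L,
                               sigma = 0.5,
                               connectivity = 26L,
                               threshold_step = 1,
                               doubling_factor = 2,
                               doubling_min_voxels = 100L,
                               threshold_floor = NULL) {
  if (window_radius < 0) stop_contract("window_radius must be >= 0")
  if (sigma < 0) stop_contract("sigma must be >= 0")
  if (!connectivity %in% c(6L, 18L, 26L))
    stop_contract("connectivity must be 6, 18 or 26")
  if (threshold_step <= 0) stop_contract("threshold_step must be > 0")
  if (doubling_factor <= 1) stop_contract("doubling_factor must be > 1")
  if (doubling_min_voxels < 1) stop_contract("doubling_min_voxels must be >= 1")
  structure(list(window_radius = as.integer(window_radius), sigma = sigma,
                 connectivity = as.integer(connectivity),
                 threshold_step = threshold_step,
                 doubling_factor = doubling_factor,
                 doubling_min_voxels = as.integer(doubling_min_voxels),
                 threshold_floor = threshold_floor),
            class = "region_grow_params")
}

## Clipped cubic window around a seed; returns index ranges per axis.
window_ranges <- function(seed, dims, radius) {
  list(i = max(1L, seed$i - radius):min(dims[1], seed$i + radius),
       j = max(1L, seed$j - radius):min(dims[2], seed$j + radius),
       k = max(1L, seed$k - radius):min(dims[3], seed$k + radius))
}

#' Correct a manual seed to the local intensity maximum
#'
#' Operators place seeds "near the plaque centre"; for reproducibility the
#' seed is moved to the voxel with the highest intensity within the cubic
#' window (default 7 x 7 x 7) centred on the manual seed, clipped at the
#' volume borders. Ties are broken deterministically by the lowest
#' `(i, j, k)` in lexicographic order.
#'
#' @param volume A [volume3d()]; by convention the smoothed volume (see
#'   [segment()] for the switch).
#' @param manual_seed A [seed_point()] inside the volume.
#' @param window_radius Window half-width in voxels (default 3).
#' @return A [seed_point()] with `kind = "corrected"`.
#' @export
correct_seed <- function(volume, manual_seed, window_radius = 3L) {
  dims <- dim(volume$data)
  check_seed_bounds(manual_seed, dims, "manual seed")
  w <- window_ranges(manual_seed, dims, as.integer(window_radius))
  sub <- volume$data[w$i, w$j, w$k, drop = FALSE]
  hits <- which(sub == max(sub), arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2], hits[, 3]), , drop = FALSE]
  seed_point(w$i[hits[1, 1]], w$j[hits[1, 2]], w$k[hits[1, 3]],
             kind = "corrected")
}

#' Initial region-growing threshold
#'
#' The starting threshold is the highest intensity within the cubic window
#' (default 7 x 7 x 7) centred on the corrected seed point, computed on the
#' smoothed volume.
#'
#' @inheritParams correct_seed
#' @param smoothed The smoothed [volume3d()].
#' @param corrected_seed A [seed_point()] inside the volume.
#' @return The window maximum (scalar intensity).
#' @export
initial_threshold <- function(smoothed, corrected_seed, window_radius = 3L) {
  dims <- dim(smoothed$data)
  check_seed_bounds(corrected_seed, dims, "corrected seed")
  w <- window_ranges(corrected_seed, dims, as.integer(window_radius))
  max(smoothed$data[w$i, w$j, w$k])
}

## 1D correlation along one axis with replicate (nearest) boundary handling;
## the kernel is symmetric so correlation equals convolution.
convolve_axis <- function(a, w, axis) {
  r <- (length(w) - 1L) %/% 2L
  n <- dim(a)[axis]
  out <- array(0, dim(a))
  for (o in -r:r) {
    idx <- pmin(pmax(seq_len(n) + o, 1L), n)
    shifted <- switch(axis,
                      a[idx, , , drop = FALSE],
                      a[, idx, , drop = FALSE],
                      a[, , idx, drop = FALSE])
    out <- out + w[o + r + 1L] * shifted
  }
  out
}

gaussian_kernel_1d <- function(sigma, radius = max(1L, ceiling(4 * sigma))) {
  x <- (-radius):radius
  w <- exp(-x^2 / (2 * sigma^2))
  w / sum(w)
}

#' Gaussian smoothing of a volume
#'
#' Separable Gaussian filter with width `sigma` in voxel units per axis,
#' truncated at 4 sigma and normalized; borders are handled by edge
#' replication. `sigma = 0` returns the input unchanged. Smoothing reduces
#' the influence of noise on the region-growing stage.
#'
#' @param volume A [volume3d()].
#' @param sigma Gaussian width in voxels, `>= 0` (default 0.5).
#' @return A smoothed [volume3d()] of identical shape and spacing.
#' @export
smooth_volume <- function(volume, sigma = 0.5) {
  if (!is.finite(sigma) || sigma < 0) stop_contract("sigma must be >= 0")
  if (sigma == 0) return(volume)
  w <- gaussian_kernel_1d(sigma)
  out <- volume$data
  for (axis in 1:3) out <- convolve_axis(out, w, axis)
  volume3d(out, volume$spacing, volume$reference)
}

#' Mean intensity of the muscle reference region
#'
#' Arithmetic mean of the *original* (unsmoothed) volume intensities over the
#' muscle ROI. The plaque-to-muscle contrast ratio that defines HSP is a
#' property of native tissue signal, so the reference mean is never taken on
#' the smoothed image.
#'
#' @param volume The original [volume3d()].
#' @param muscle_roi A nonempty [mask3d()] of the same shape.
#' @return Scalar mean intensity.
#' @export
muscle_mean <- function(volume, muscle_roi) {
  if (!inherits(muscle_roi, "mask3d")) stop_contract("muscle_roi must be a mask3d")
  check_same_shape(dim(muscle_roi$data), dim(volume$data), "muscle ROI")
  n <- sum(muscle_roi$data)
  if (n == 0L) stop_contract("muscle ROI is empty")
  mean(volume$data[muscle_roi$data])
}

#' Segment the high-signal plaque within the plaque region
#'
#' Keeps the plaque voxels whose original intensity strictly exceeds
#' `muscle_mean * coefficient`. The default coefficient 1.3 separates
#' high-signal (unstable: hemorrhagic or lipid-rich/necrotic) from fibrous
#' plaque; 1.52 is the published cutoff separating intraplaque hemorrhage
#' from lipid-rich/necrotic tissue and may be supplied instead, though no
#' IPH-specific validation is claimed here.
#'
#' @param volume The original [volume3d()].
#' @param plaque_mask [mask3d()] of the extracted plaque region.
#' @param muscle_mean Mean muscle intensity from [muscle_mean()].
#' @param coefficient Positive contrast-ratio cutoff (default 1.3).
#' @return A list with `mask` (the HSP [mask3d()], a subset of
#'   `plaque_mask`) and `threshold` (`muscle_mean * coefficient`).
#' @export
segment_hsp <- function(volume, plaque_mask, muscle_mean, coefficient = 1.3) {
  if (!inherits(plaque_mask, "mask3d")) stop_contract("plaque_mask must be a mask3d")
  check_same_shape(dim(plaque_mask$data), dim(volume$data), "plaque mask")
  if (!is.finite(coefficient) || coefficient <= 0)
    stop_contract("coefficient must be > 0")
  thr <- muscle_mean * coefficient
  m <- plaque_mask$data & (volume$data > thr)
  list(mask = mask3d(m, plaque_mask$spacing), threshold = thr)
}

#' Mask volume in cubic millimetres
#'
#' `voxel_sum` multiplies the voxel count by the voxel volume
#' `dx * dy * dz`. `slice_area` sums the in-plane area
#' (in-slice count times `dx * dy`) over slices and multiplies by the slice
#' thickness `dz` — the convention used for manual planimetric measurement.
#' On a regular grid the two coincide.
#'
#' @param mask A [mask3d()].
#' @param spacing Optional spacing override (mm); defaults to the mask's.
#' @param method `"voxel_sum"` (default) or `"slice_area"`.
#' @return Volume in mm^3.
#' @export
compute_volume <- function(mask, spacing = NULL,
                           method = c("voxel_sum", "slice_area")) {
  method <- match.arg(method)
  if (!inherits(mask, "mask3d")) stop_contract("compute_volume: need a mask3d")
  sp <- as.numeric(spacing %||% mask$spacing)
  if (length(sp) != 3L || any(sp <= 0))
    stop_contract("spacing must be three positive numbers (mm)")
  if (method == "voxel_sum") {
    sum(mask$data) * prod(sp)
  } else {
    counts <- apply(mask$data, 3, sum)
    sum(counts * sp[1] * sp[2]) * sp[3]
  }
}
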