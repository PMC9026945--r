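#' Full semiautomated HSP segmentation
#'
#' Runs the two-stage pipeline end to end:
#'
#' 1. *Plaque extraction.* The volume is Gaussian-smoothed
#'    ([smooth_volume()]); the manual seed is corrected to the local maximum
#'    of a cubic window ([correct_seed()]); the region is grown with a
#'    stepwise-decreasing threshold starting at the window maximum
#'    ([grow_plaque_region()]).
#' 2. *HSP segmentation.* The mean of the original intensities over the
#'    muscle reference ROI ([muscle_mean()]) times `coefficient` (default
#'    1.3) thresholds the original intensities within the plaque region
#'    ([segment_hsp()]).
#'
#' Plaque and HSP volumes are reported in mm^3 ([compute_volume()]). The
#' pipeline contains no randomness: identical inputs give identical outputs.
#'
#' @param volume The original [volume3d()].
#' @param manual_seed A [seed_point()] near the plaque centre.
#' @param muscle_roi A nonempty [mask3d()] over adjacent muscle tissue, or
#'   `NULL` together with `muscle_sphere`.
#' @param params A [region_grow_params()].
#' @param coefficient Contrast-ratio cutoff for HSP (default 1.3; use 1.52
#'   to target intraplaque hemorrhage specifically).
#' @param muscle_sphere Alternative ROI specification: `c(i, j, k, r_mm)`, a
#'   sphere centre in voxel coordinates plus a radius in mm, rasterized by
#'   [sphere_roi()].
#' @param seed_on_smoothed Correct the seed on the smoothed (default) or
#'   original volume.
#' @param volume_method Volumetry convention passed to [compute_volume()].
#' @return An object of class `hsp_segmentation`: a list with
#'   `plaque_mask`, `hsp_mask`, `corrected_seed`, `initial_threshold`,
#'   `final_threshold`, `muscle_mean`, `hsp_threshold`, `coefficient`,
#'   `plaque_volume_mm3`, `hsp_volume_mm3`, `trace` and `stop_reason`.
#' @examples
#' ph <- generate_phantom(phantom_spec(noise_sd = 0))
#' res <- segment(ph$volume, ph$manual_seed, ph$muscle_roi)
#' res
#' dice(res$hsp_mask, ph$hsp_truth)
#' @export
segment <- function(volume, manual_seed, muscle_roi = NULL,
                    params = region_grow_params(), coefficient = 1.3,
                    muscle_sphere = NULL,
                    seed_on_smoothed = TRUE,
                    volume_method = c("voxel_sum", "slice_area")) {
  volume_method <- match.arg(volume_method)
  if (!inherits(volume, "volume3d")) stop_contract("segment: need a volume3d")
  if (!inherits(manual_seed, "seed_point"))
    stop_contract("segment: manual_seed must be a seed_point")
  if (is.null(muscle_roi)) {
    if (is.null(muscle_sphere))
      stop_contract("segment: provide muscle_roi or muscle_sphere")
    if (length(muscle_sphere) != 4L)
      stop_contract("muscle_sphere must be c(i, j, k, r_mm)")
    muscle_roi <- sphere_roi(volume, muscle_sphere[1:3], muscle_sphere[4])
  }

  smoothed <- smooth_volume(volume, params$sigma)
  seed_vol <- if (seed_on_smoothed) smoothed else volume
  corrected <- correct_seed(seed_vol, manual_seed, params$window_radius)
  grown <- grow_plaque_region(smoothed, corrected, params)
  mm <- muscle_mean(volume, muscle_roi)
  hsp <- segment_hsp(volume, grown$mask, mm, coefficient)

  structure(list(
    plaque_mask = grown$mask,
    hsp_mask = hsp$mask,
    corrected_seed = corrected,
    initial_threshold = grown$initial_threshold,
    final_threshold = grown$final_threshold,
    muscle_mean = mm,
    hsp_threshold = hsp$threshold,
    coefficient = coefficient,
    plaque_volume_mm3 = compute_volume(grown$mask, method = volume_method),
    hsp_volume_mm3 = compute_volume(hsp$mask, method = volume_method),
    trace = grown$trace,
    stop_reason = attr(grown$trace, "stop_reason"),
    params = params
  ), class = "hsp_segmentation")
}

#' @export
print.hsp_segmentation <- function(x, ...) {
  cat("Semiautomated HSP segmentation\n")
  cat(sprintf("  corrected seed      : (%d, %d, %d)\n",
              x$corrected_seed$i, x$corrected_seed$j, x$corrected_seed$k))
  cat(sprintf("  growing threshold   : %.6g -> %.6g (%s, %d passes)\n",
              x$initial_threshold, x$final_threshold, x$stop_reason,
              nrow(x$trace)))
  cat(sprintf("  muscle mean         : %.6g\n", x$muscle_mean))
  cat(sprintf("  HSP threshold       : %.6g (coefficient %.4g)\n",
              x$hsp_threshold, x$coefficient))
  cat(sprintf("  plaque volume       : %.4f mm^3 (%d voxels)\n",
              x$plaque_volume_mm3, sum(x$plaque_mask$data)))
  cat(sprintf("  HSP volume          : %.4f mm^3 (%d voxels)\n",
              x$hsp_volume_mm3, sum(x$hsp_mask$data)))
  invisible(x)
}
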