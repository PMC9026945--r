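#' Synthetic vessel-wall phantom specification
#'
#' Describes a digital phantom that emulates the geometry and contrast of a
#' carotid plaque with a high-signal core on 3D T1-weighted black-blood
#' vessel-wall MRI: an ellipsoidal plaque rim enclosing a brighter
#' ellipsoidal core, a cuboidal block of adjacent muscle as the contrast
#' reference, a darker background, and additive Gaussian noise. Intensities
#' follow the contrast-ratio ordering that defines plaque types: the rim sits
#' below 1.3x the muscle mean (fibrous-like), the core above it — by default
#' at 1.55x, beyond the 1.52 cutoff associated with intraplaque hemorrhage.
#'
#' Defaults use the acquisition geometry of 3D TSE vessel-wall imaging
#' (reconstructed in-plane resolution 0.45 mm, slice thickness 0.9 mm) and a
#' noise standard deviation of 2% of the muscle mean.
#'
#' @param shape Grid dimensions in voxels.
#' @param spacing Voxel spacing `(dx, dy, dz)` in mm.
#' @param background_mean,muscle_mean,rim_intensity,core_intensity Tissue
#'   intensities (arbitrary scanner-like units).
#' @param center Plaque centre in (possibly fractional) voxel coordinates.
#' @param core_semiaxes_mm,rim_semiaxes_mm Ellipsoid semi-axes in mm; the
#'   core ellipsoid must lie inside the rim ellipsoid.
#' @param muscle_center,muscle_halfsize Centre and half-extents (voxels) of
#'   the muscle block; the ROI handed back for the reference mean.
#' @param noise_sd Standard deviation of additive Gaussian noise, `>= 0`.
#' @param rng_seed Integer seed making generation deterministic.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 32L),
                         spacing = c(0.45, 0.45, 0.9),
                         background_mean = 350,
                         muscle_mean = 500,
                         rim_intensity = 590,
                         core_intensity = 775,
                         center = c(32, 32, 16),
                         core_semiaxes_mm = c(3, 3, 3.6),
                         rim_semiaxes_mm = c(4.5, 4.5, 5.4),
                         muscle_center = c(50, 16, 16),
                         muscle_halfsize = c(4L, 4L, 2L),
                         noise_sd = 10,
                         rng_seed = 1L) {
  spec <- structure(as.list(environment()), class = "phantom_spec")
  if (any(shape < 8)) stop_contract("phantom grid must be at least 8 voxels per axis")
  if (any(spacing <= 0)) stop_contract("spacing must be positive")
  if (noise_sd < 0) stop_contract("noise_sd must be >= 0")
  if (any(core_semiaxes_mm >= rim_semiaxes_mm))
    stop_contract("core ellipsoid must lie strictly inside the rim ellipsoid")
  if (core_intensity <= 1.3 * muscle_mean)
    stop_contract("core intensity must exceed 1.3 x muscle mean (high-signal core)")
  if (rim_intensity >= 1.3 * muscle_mean)
    stop_contract("rim intensity must stay below 1.3 x muscle mean (fibrous-like rim)")
  if (rim_intensity <= muscle_mean || core_intensity <= rim_intensity)
    stop_contract("intensities must be ordered background < muscle < rim < core")
  spec
}

## Ellipsoid rasterized by voxel-centre inclusion, distances in mm.
ellipsoid_mask <- function(shape, spacing, center, semiaxes_mm) {
  u <- lapply(1:3, function(a)
    ((seq_len(shape[a]) - center[a]) * spacing[a] / semiaxes_mm[a])^2)
  q <- outer(outer(u[[1]], u[[2]], `+`), u[[3]], `+`)
  q <= 1
}

#' Generate a synthetic vessel-wall phantom with ground truth
#'
#' Rasterizes the geometry of a [phantom_spec()] (voxel-centre inclusion),
#' paints tissue intensities, adds Gaussian noise, and returns the volume
#' together with the ground-truth masks needed to validate segmentation:
#' `plaque_truth` (rim and core), `hsp_truth` (the core), and the muscle ROI.
#' The manual seed emulates operator behaviour: a random core voxel
#' perturbed by up to 2 voxels per axis, constrained to remain inside the
#' plaque. Generation is deterministic given `rng_seed`.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `volume` ([volume3d()]), `plaque_truth`, `hsp_truth`,
#'   `muscle_roi` (all [mask3d()]), `manual_seed` ([seed_point()]) and
#'   `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec")) stop_contract("need a phantom_spec")
  shape <- as.integer(spec$shape); sp <- spec$spacing
  core <- ellipsoid_mask(shape, sp, spec$center, spec$core_semiaxes_mm)
  rim  <- ellipsoid_mask(shape, sp, spec$center, spec$rim_semiaxes_mm)
  if (!all(rim[core])) stop_contract("rasterized core escapes the rim")
  if (!any(core)) stop_contract("core ellipsoid rasterizes to an empty mask")

  mc <- spec$muscle_center; mh <- spec$muscle_halfsize
  mi <- max(1L, mc[1] - mh[1]):min(shape[1], mc[1] + mh[1])
  mj <- max(1L, mc[2] - mh[2]):min(shape[2], mc[2] + mh[2])
  mk <- max(1L, mc[3] - mh[3]):min(shape[3], mc[3] + mh[3])
  muscle <- array(FALSE, shape)
  muscle[mi, mj, mk] <- TRUE
  if (any(muscle & rim))
    stop_contract("muscle block overlaps the plaque; move it")

  img <- array(spec$background_mean, shape)
  img[muscle] <- spec$muscle_mean
  img[rim] <- spec$rim_intensity
  img[core] <- spec$core_intensity

  with_seed(spec$rng_seed, {
    if (spec$noise_sd > 0)
      img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd), shape)
    core_idx <- which(core, arr.ind = TRUE)
    repeat {
      base <- core_idx[sample.int(nrow(core_idx), 1L), ]
      cand <- base + sample(-2:2, 3L, replace = TRUE)
      if (all(cand >= 1L) && all(cand <= shape) &&
          rim[cand[1], cand[2], cand[3]]) break
    }
  })

  list(volume = volume3d(img, sp),
       plaque_truth = mask3d(rim, sp),
       hsp_truth = mask3d(core, sp),
       muscle_roi = mask3d(muscle, sp),
       manual_seed = seed_point(cand[1], cand[2], cand[3], kind = "manual"),
       spec = spec)
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(code))
}

#' Dice similarity coefficient of two masks
#'
#' `2|A & B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b [mask3d()] objects of identical shape.
#' @return Overlap ratio in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!inherits(a, "mask3d") || !inherits(b, "mask3d"))
    stop_contract("dice: need two mask3d objects")
  check_same_shape(dim(a$data), dim(b$data), "mask")
  na <- sum(a$data); nb <- sum(b$data)
  if (na + nb == 0L) return(1)
  2 * sum(a$data & b$data) / (na + nb)
}
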