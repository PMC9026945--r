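#' 3D image volume with voxel spacing
#'
#' A `volume3d` bundles a 3D numeric array with its voxel spacing in mm and,
#' when the volume came from disk, the source NIfTI image so that orientation
#' metadata can be passed through unchanged to any mask written against it.
#' The array is used in native voxel space throughout; nothing is resampled.
#'
#' @param data 3D numeric array of finite intensities.
#' @param spacing Numeric length-3 vector `(dx, dy, dz)` in mm, all `> 0`.
#' @param reference Optional `niftiImage` whose header is reused on write.
#'
#' @return An object of class `volume3d` with elements `data`, `spacing`
#'   and `reference`.
#' @seealso [read_volume()], [write_mask()]
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), reference = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_contract("volume3d: `data` must be a 3D array")
  if (any(dim(data) < 1L))
    stop_contract("volume3d: all three dimensions must be >= 1")
  if (!all(is.finite(data)))
    stop_data("volume3d: data contains non-finite values")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_contract("volume3d: spacing must be three positive numbers (mm)")
  data <- array(as.double(data), dim = dim(data))  # plain array, no stray attrs
  structure(list(data = data, spacing = spacing, reference = reference),
            class = "volume3d")
}

#' Binary 3D mask aligned to a volume
#'
#' @param data 3D array coercible to logical (values 0/1), same shape as the
#'   parent volume.
#' @param spacing Voxel spacing in mm, inherited from the parent volume.
#' @return An object of class `mask3d` with a logical `data` array.
#' @export
mask3d <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_contract("mask3d: `data` must be a 3D array")
  if (is.numeric(data) && !all(data %in% c(0, 1)))
    stop_contract("mask3d: values must be 0/1")
  d <- array(as.logical(data), dim = dim(data))
  if (anyNA(d)) stop_contract("mask3d: values must be 0/1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop_contract("mask3d: spacing must be three positive numbers (mm)")
  structure(list(data = d, spacing = spacing), class = "mask3d")
}

#' Seed point in voxel coordinates
#'
#' Voxel indices are 1-based `(i, j, k)` in array index order. A seed is
#' either `manual` (as placed by the operator) or `corrected` (moved to the
#' brightest voxel of the search window by [correct_seed()]).
#'
#' @param i,j,k Integer voxel indices (1-based).
#' @param kind `"manual"` or `"corrected"`.
#' @return An object of class `seed_point`.
#' @export
seed_point <- function(i, j, k, kind = c("manual", "corrected")) {
  kind <- match.arg(kind)
  ijk <- c(i, j, k)
  if (length(ijk) != 3L || any(!is.finite(ijk)) || any(ijk != round(ijk)))
    stop_contract("seed_point: i, j, k must be integer voxel indices")
  structure(list(i = as.integer(i), j = as.integer(j), k = as.integer(k),
                 kind = kind), class = "seed_point")
}

check_seed_bounds <- function(seed, dims, what = "seed") {
  ijk <- c(seed$i, seed$j, seed$k)
  if (any(ijk < 1L) || any(ijk > dims))
    stop_contract(sprintf(
      "%s (%d, %d, %d) is outside the volume extent (%d x %d x %d)",
      what, seed$i, seed$j, seed$k, dims[1], dims[2], dims[3]))
  invisible(seed)
}

check_same_shape <- function(a_dim, b_dim, what = "mask") {
  if (!identical(as.integer(a_dim), as.integer(b_dim)))
    stop_contract(sprintf("%s shape (%s) does not match volume shape (%s)",
                          what, paste(a_dim, collapse = "x"),
                          paste(b_dim, collapse = "x")))
  invisible(TRUE)
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("volume3d: %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.mask3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("mask3d: %d x %d x %d voxels, %d foreground (%.4g mm^3)\n",
              d[1], d[2], d[3], sum(x$data),
              sum(x$data) * prod(x$spacing)))
  invisible(x)
}

#' @export
print.seed_point <- function(x, ...) {
  cat(sprintf("seed_point (%s): (%d, %d, %d)\n", x$kind, x$i, x$j, x$k))
  invisible(x)
}

#' Rasterize a spherical region of interest
#'
#' Builds a binary mask of the sphere of radius `radius_mm` centred at voxel
#' coordinates `center` (which may be fractional), by voxel-centre inclusion:
#' a voxel belongs to the sphere when its centre lies within `radius_mm` of
#' the sphere centre, with distances measured in mm using the volume spacing.
#' Used for muscle reference ROIs specified as `center + radius` rather than
#' as a mask file.
#'
#' @param volume A [volume3d()].
#' @param center Numeric length-3 voxel coordinates (1-based) of the centre.
#' @param radius_mm Sphere radius in mm, `> 0`.
#' @return A [mask3d()] with the rasterized sphere.
#' @export
sphere_roi <- function(volume, center, radius_mm) {
  if (!inherits(volume, "volume3d")) stop_contract("sphere_roi: need a volume3d")
  center <- as.numeric(center)
  if (length(center) != 3L || any(!is.finite(center)))
    stop_contract("sphere_roi: center must be three voxel coordinates")
  if (!is.finite(radius_mm) || radius_mm <= 0)
    stop_contract("sphere_roi: radius_mm must be > 0")
  d <- dim(volume$data); sp <- volume$spacing
  dx2 <- outer((seq_len(d[1]) - center[1]) * sp[1], rep(0, d[2]), `+`)^2 +
         outer(rep(0, d[1]), (seq_len(d[2]) - center[2]) * sp[2], `+`)^2
  m <- array(FALSE, d)
  for (k in seq_len(d[3])) {
    zk2 <- ((k - center[3]) * sp[3])^2
    m[, , k] <- dx2 + zk2 <= radius_mm^2
  }
  mask3d(m, volume$spacing)
}
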