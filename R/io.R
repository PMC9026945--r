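#' Read a 3D volume from a NIfTI file
#'
#' Loads a NIfTI-1 image (`.nii` or `.nii.gz`) as a [volume3d()], taking the
#' voxel spacing from the header `pixdim`. 4D images holding a single frame
#' are squeezed to 3D. Orientation metadata is retained opaquely and reused
#' verbatim when masks are written against this volume; the segmentation
#' itself operates purely in voxel space.
#'
#' @param path Path to a readable NIfTI file containing a 3D image.
#' @return A [volume3d()].
#' @export
read_volume <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop_io(sprintf("cannot read volume: file not found: %s", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop_io(sprintf(
                    "cannot read NIfTI file %s: %s", path, conditionMessage(e))))
  arr <- as.array(img)
  d <- dim(arr)
  ## squeeze trailing singleton dimensions of a single-frame 4D+ image
  if (length(d) > 3L) {
    if (prod(d[-(1:3)]) != 1L)
      stop_contract(sprintf("%s is %dD with %d frames; a single 3D image is required",
                            path, length(d), prod(d[-(1:3)])))
    arr <- array(arr, dim = d[1:3])
  }
  if (length(dim(arr)) != 3L)
    stop_contract(sprintf("%s is %dD; a 3D image is required", path, length(dim(arr))))
  if (!all(is.finite(arr)))
    stop_data(sprintf("%s contains non-finite voxel values", path))
  sp <- RNifti::pixdim(img)[1:3]
  volume3d(arr, spacing = sp, reference = img)
}

#' Write a binary mask as NIfTI against a reference volume
#'
#' The mask is stored as an unsigned 8-bit 0/1 image carrying the reference
#' volume's spacing and orientation metadata, so it overlays the source image
#' in any NIfTI viewer.
#'
#' @param mask A [mask3d()] with the same shape as `reference`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param reference The [volume3d()] the mask belongs to.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, reference) {
  if (!inherits(mask, "mask3d")) stop_contract("write_mask: need a mask3d")
  if (!inherits(reference, "volume3d")) stop_contract("write_mask: need a volume3d reference")
  check_same_shape(dim(mask$data), dim(reference$data), "mask")
  payload <- array(as.integer(mask$data), dim = dim(mask$data))
  img <- if (!is.null(reference$reference)) {
    RNifti::asNifti(payload, reference = reference$reference)
  } else {
    im <- RNifti::asNifti(payload)
    RNifti::pixdim(im) <- reference$spacing
    im
  }
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Write a volume as NIfTI
#'
#' Stores intensities as float64 so that written and reread data are
#' bit-identical; used mainly to persist synthetic phantoms.
#'
#' @param volume A [volume3d()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  if (!inherits(volume, "volume3d")) stop_contract("write_volume: need a volume3d")
  img <- if (!is.null(volume$reference)) {
    RNifti::asNifti(volume$data, reference = volume$reference)
  } else {
    im <- RNifti::asNifti(volume$data)
    RNifti::pixdim(im) <- volume$spacing
    im
  }
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a binary mask from a NIfTI file
#'
#' @param path Path to a NIfTI mask with values 0/1.
#' @param reference Optional [volume3d()] whose shape the mask must match.
#' @return A [mask3d()].
#' @export
read_mask <- function(path, reference = NULL) {
  vol <- read_volume(path)
  if (!all(vol$data %in% c(0, 1)))
    stop_data(sprintf("%s is not a binary 0/1 mask", path))
  if (!is.null(reference))
    check_same_shape(dim(vol$data), dim(reference$data), basename(path))
  mask3d(vol$data, vol$spacing)
}
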