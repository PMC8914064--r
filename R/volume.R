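#' Construct a CT volume with an aligned lesion mask
#'
#' The elementary image container of the package: a 3D grid of intensities in
#' Hounsfield units, a binary lesion mask on the same grid, and the physical
#' voxel spacing in millimetres. Voxel centre `(i, j, k)` (1-based) sits at
#' physical position `((i-1) s_x, (j-1) s_y, (k-1) s_z)`.
#'
#' @param image 3D numeric array of intensities (HU).
#' @param mask 3D array of the same shape; nonzero marks lesion voxels.
#' @param spacing Numeric length-3, millimetres per voxel along each axis.
#' @return An object of class `rad_volume`.
#' @export
rad_volume <- function(image, mask, spacing) {
  if (length(dim(image)) != 3L) abort("`image` must be a 3D array.")
  if (!identical(dim(image), dim(mask))) {
    abort("`image` and `mask` must have identical dimensions.")
  }
  check_positive(spacing, "spacing")
  if (length(spacing) != 3L) abort("`spacing` must have length 3.")
  mask <- array(as.logical(mask != 0), dim = dim(mask))
  if (!any(mask)) abort("`mask` is empty: no lesion voxels.")
  structure(
    list(image = image, mask = mask, spacing = as.numeric(spacing)),
    class = "rad_volume"
  )
}

#' @export
print.rad_volume <- function(x, ...) {
  cat(sprintf(
    "<rad_volume> %s voxels @ %s mm, %d mask voxels (%.1f mm^3)\n",
    paste(dim(x$image), collapse = "x"),
    paste(format(x$spacing, trim = TRUE), collapse = "x"),
    sum(x$mask), sum(x$mask) * prod(x$spacing)
  ))
  invisible(x)
}

# physical coordinates (mm) of all mask voxel centres, one row per voxel
mask_coords <- function(vm) {
  idx <- which(vm$mask, arr.ind = TRUE)
  sweep(idx - 1, 2, vm$spacing, `*`)
}

#' Read an image/mask pair from NIfTI files
#'
#' @param image_path,mask_path Paths to NIfTI files holding the intensity
#'   volume and the binary lesion mask on the same grid.
#' @return A [rad_volume()].
#' @export
read_volume <- function(image_path, mask_path) {
  img <- RNifti::readNifti(image_path)
  msk <- RNifti::readNifti(mask_path)
  sp <- RNifti::pixdim(img)[1:3]
  rad_volume(array(as.numeric(img), dim = dim(img)),
             array(as.numeric(msk), dim = dim(msk)), sp)
}

#' Write an image/mask pair to NIfTI files
#'
#' @param vm A [rad_volume()].
#' @param image_path,mask_path Output paths (`.nii` or `.nii.gz`).
#' @return `vm`, invisibly.
#' @export
write_volume <- function(vm, image_path, mask_path) {
  img <- RNifti::asNifti(vm$image)
  RNifti::pixdim(img) <- vm$spacing
  msk <- RNifti::asNifti(array(as.integer(vm$mask), dim = dim(vm$mask)))
  RNifti::pixdim(msk) <- vm$spacing
  RNifti::writeNifti(img, image_path)
  RNifti::writeNifti(msk, mask_path)
  invisible(vm)
}
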