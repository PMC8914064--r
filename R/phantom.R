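#' Specify a synthetic lesion phantom
#'
#' Describes a voxel grid and an analytic lesion: a sphere, an ellipsoid, or
#' a "textured blob" (an ellipsoid whose radius is modulated by a smooth
#' angular perturbation and whose interior carries a smooth random intensity
#' texture). Phantoms stand in for contrast-enhanced CT acquisitions of
#' bladder lesions, so defaults use soft-tissue Hounsfield levels.
#'
#' @param grid_shape Integer length-3, voxels per axis.
#' @param spacing Numeric length-3, mm per voxel (strictly positive).
#' @param lesion_kind `"sphere"`, `"ellipsoid"` or `"textured_blob"`.
#' @param radii Lesion semi-axes in mm (length 1 or 3; a sphere uses the
#'   first value).
#' @param center Lesion centre in mm, in grid coordinates where voxel
#'   `(1,1,1)` sits at the origin; default is the grid centre.
#' @param background_hu,lesion_hu Intensity of background and lesion (HU).
#' @param noise_sd Additive white Gaussian noise, HU.
#' @param texture_amp Amplitude (HU) of the smooth interior texture used by
#'   `"textured_blob"`.
#' @param seed Integer seed; all phantom randomness derives from it.
#' @return A validated spec of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(48L, 48L, 32L),
                         spacing = c(1, 1, 1),
                         lesion_kind = c("sphere", "ellipsoid", "textured_blob"),
                         radii = 10,
                         center = NULL,
                         background_hu = -20,
                         lesion_hu = 45,
                         noise_sd = 0,
                         texture_amp = 25,
                         seed = 1L) {
  lesion_kind <- match.arg(lesion_kind)
  check_positive(spacing, "spacing")
  if (length(spacing) != 3L) abort("`spacing` must have length 3.")
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 2L)) {
    abort("`grid_shape` must be three integers >= 2.")
  }
  check_positive(radii, "radii")
  radii <- rep_len(as.numeric(radii), 3L)
  extent <- (grid_shape - 1) * spacing
  if (is.null(center)) center <- extent / 2
  center <- as.numeric(center)
  if (length(center) != 3L) abort("`center` must have length 3.")
  # the blob's angular modulation can push the radius up to 20% outward
  reach <- radii * if (lesion_kind == "textured_blob") 1.2 else 1
  if (any(center - reach < 0) || any(center + reach > extent)) {
    abort(paste0(
      "Lesion does not fit inside the grid: centre ",
      paste(format(center), collapse = ", "), " mm with reach ",
      paste(format(reach), collapse = ", "), " mm exceeds the grid extent ",
      paste(format(extent), collapse = ", "), " mm."
    ))
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  structure(
    list(grid_shape = grid_shape, spacing = as.numeric(spacing),
         lesion_kind = lesion_kind, radii = radii, center = center,
         background_hu = background_hu, lesion_hu = lesion_hu,
         noise_sd = noise_sd, texture_amp = texture_amp,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Generate a lesion phantom
#'
#' Builds the intensity volume and binary mask described by a
#' [phantom_spec()]. Mask voxels are exactly those whose centre lies inside
#' the analytic lesion surface; the result is deterministic given the spec's
#' seed.
#'
#' @param spec A [phantom_spec()].
#' @return A [rad_volume()].
#' @examples
#' vm <- make_phantom(phantom_spec(radii = 8))
#' sum(vm$mask) * prod(vm$spacing)  # close to 4/3 * pi * 8^3
#' @export
make_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) abort("`spec` must be a phantom_spec.")
  d <- spec$grid_shape
  ax <- lapply(1:3, function(a) ((seq_len(d[a]) - 1) * spec$spacing[a]) - spec$center[a])
  # normalized coordinates relative to the semi-axes, as 3D arrays
  gx <- array(ax[[1]], dim = d)
  gy <- aperm(array(ax[[2]], dim = d[c(2, 1, 3)]), c(2, 1, 3))
  gz <- aperm(array(ax[[3]], dim = d[c(3, 1, 2)]), c(2, 3, 1))

  r <- sqrt(gx^2 + gy^2 + gz^2)
  if (spec$lesion_kind == "textured_blob") {
    # smooth angular modulation of the ellipsoid radius, phases from the seed
    ph <- with_seed(derive_seed(spec$seed, 1L), runif(3, 0, 2 * pi))
    theta <- acos(ifelse(r > 0, pmin(1, pmax(-1, gz / pmax(r, 1e-12))), 1))
    phi <- atan2(gy, gx)
    mod <- 1 + 0.12 * sin(2 * theta + ph[1]) * cos(2 * phi + ph[2]) +
      0.08 * cos(3 * phi + ph[3])
  } else {
    mod <- 1
  }
  u2 <- (gx / (spec$radii[1] * mod))^2 + (gy / (spec$radii[2] * mod))^2 +
    (gz / (spec$radii[3] * mod))^2
  mask <- u2 <= 1
  if (!any(mask)) abort("Lesion mask is empty on this grid.")

  image <- array(spec$background_hu, dim = d)
  image[mask] <- spec$lesion_hu
  if (spec$lesion_kind == "textured_blob" && spec$texture_amp > 0) {
    tex <- with_seed(derive_seed(spec$seed, 2L),
                     array(rnorm(prod(d)), dim = d))
    tex <- box_smooth3(tex, width = 5L)
    tex <- tex / max(sd(tex[mask]), 1e-12) * spec$texture_amp
    image[mask] <- image[mask] + tex[mask]
  }
  if (spec$noise_sd > 0) {
    image <- image + with_seed(derive_seed(spec$seed, 3L),
                               array(rnorm(prod(d), sd = spec$noise_sd), dim = d))
  }
  rad_volume(image, mask, spec$spacing)
}

# separable moving-average smoother with edge replication, used for the
# blob's interior texture
box_smooth3 <- function(arr, width = 5L) {
  half <- width %/% 2L
  smooth_axis <- function(a, axis) {
    d <- dim(a)
    idx <- lapply(seq(-half, half), function(s) {
      pmin(pmax(seq_len(d[axis]) + s, 1L), d[axis])
    })
    out <- array(0, dim = d)
    for (ix in idx) {
      sl <- switch(axis, a[ix, , , drop = FALSE], a[, ix, , drop = FALSE],
                   a[, , ix, drop = FALSE])
      out <- out + sl
    }
    out / length(idx)
  }
  for (axis in 1:3) arr <- smooth_axis(arr, axis)
  arr
}
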