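#' Resample a volume to a target voxel spacing
#'
#' Intensities are resampled by trilinear interpolation and the mask by
#' nearest neighbour, on an output grid whose voxel centres span the same
#' physical extent as the input (centre of voxel `(1,1,1)` at the origin).
#' The default target, 1 x 1 x 2 mm, is the spacing the analysis pipeline
#' standardizes CT acquisitions to before feature extraction.
#'
#' @param vm A [rad_volume()].
#' @param target_spacing Numeric length-3, mm.
#' @return A [rad_volume()] at the target spacing.
#' @export
resample_volume <- function(vm, target_spacing = c(1, 1, 2)) {
  check_positive(target_spacing, "target_spacing")
  if (length(target_spacing) != 3L) abort("`target_spacing` must have length 3.")
  sp <- vm$spacing; tsp <- as.numeric(target_spacing)
  d <- dim(vm$image)
  if (isTRUE(all.equal(sp, tsp))) {
    return(vm)
  }
  extent <- (d - 1) * sp
  d_out <- pmax(2L, floor(extent / tsp) + 1L)

  # continuous input indices (1-based) of each output voxel centre, per axis
  ax_idx <- lapply(1:3, function(a) {
    x <- (seq_len(d_out[a]) - 1) * tsp[a]
    pmin(pmax(x / sp[a] + 1, 1), d[a])
  })
  gx <- array(ax_idx[[1]], dim = d_out)
  gy <- aperm(array(ax_idx[[2]], dim = d_out[c(2, 1, 3)]), c(2, 1, 3))
  gz <- aperm(array(ax_idx[[3]], dim = d_out[c(3, 1, 2)]), c(2, 3, 1))

  i0 <- pmin(floor(gx), d[1] - 1L); fx <- gx - i0
  j0 <- pmin(floor(gy), d[2] - 1L); fy <- gy - j0
  k0 <- pmin(floor(gz), d[3] - 1L); fz <- gz - k0

  gather <- function(di, dj, dk) {
    vm$image[cbind(as.vector(i0 + di), as.vector(j0 + dj), as.vector(k0 + dk))]
  }
  img <- (1 - fx) * (1 - fy) * (1 - fz) * gather(0, 0, 0) +
    fx * (1 - fy) * (1 - fz) * gather(1, 0, 0) +
    (1 - fx) * fy * (1 - fz) * gather(0, 1, 0) +
    fx * fy * (1 - fz) * gather(1, 1, 0) +
    (1 - fx) * (1 - fy) * fz * gather(0, 0, 1) +
    fx * (1 - fy) * fz * gather(1, 0, 1) +
    (1 - fx) * fy * fz * gather(0, 1, 1) +
    fx * fy * fz * gather(1, 1, 1)
  img <- array(img, dim = d_out)

  nn <- cbind(as.vector(round(gx)), as.vector(round(gy)), as.vector(round(gz)))
  msk <- array(vm$mask[nn], dim = d_out)
  if (!any(msk)) {
    abort("Mask is empty after resampling; target spacing is too coarse for this lesion.")
  }
  rad_volume(img, msk, tsp)
}

#' Discretize ROI intensities into fixed-width bins
#'
#' Maps each in-mask intensity to a grey level
#' `floor((I - min_ROI) / bin_width) + 1`, the min-referenced fixed-bin-width
#' scheme all texture families operate on. Levels outside the mask are `NA`.
#'
#' @param vm A [rad_volume()].
#' @param bin_width Bin width in HU (default 25, the conventional CT
#'   radiomics choice).
#' @return A list of class `rad_discretized`: `levels` (3D integer array,
#'   `NA` outside the mask), `n_levels` (highest level), `histogram`
#'   (tibble `level`, `count`), `bin_width`, `min_roi`, plus the source
#'   `mask` and `spacing`.
#' @export
discretize_volume <- function(vm, bin_width = 25) {
  check_positive(bin_width, "bin_width")
  vals <- vm$image[vm$mask]
  mn <- min(vals)
  lv <- as.integer(floor((vals - mn) / bin_width) + 1)
  levels <- array(NA_integer_, dim = dim(vm$image))
  levels[vm$mask] <- lv
  counts <- tabulate(lv, nbins = max(lv))
  structure(
    list(levels = levels, n_levels = max(lv),
         histogram = tibble(level = seq_along(counts), count = counts),
         bin_width = bin_width, min_roi = mn,
         mask = vm$mask, spacing = vm$spacing),
    class = "rad_discretized"
  )
}
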