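#' First-order (histogram) features of the ROI intensities
#'
#' Eighteen statistics of the in-mask intensity distribution. Entropy and
#' Uniformity operate on the fixed-bin-width discretization of the ROI
#' (see [discretize_volume()]); everything else uses the raw HU values.
#' Percentiles use linear interpolation. Skewness is the standardized third
#' moment and Kurtosis the (non-excess) fourth; both are 0 for a constant
#' ROI.
#'
#' @param vm A [rad_volume()].
#' @param disc Optional `rad_discretized` for the same volume (recomputed
#'   with `bin_width` when omitted).
#' @param bin_width Bin width in HU used when `disc` is missing.
#' @return Named numeric vector of the 18 `firstorder_*` features.
#' @export
extract_firstorder <- function(vm, disc = NULL, bin_width = 25) {
  x <- vm$image[vm$mask]
  n <- length(x)
  if (is.null(disc)) disc <- discretize_volume(vm, bin_width)
  p <- disc$histogram$count / n
  p <- p[p > 0]

  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  p10 <- unname(quantile(x, 0.10, type = 7))
  p90 <- unname(quantile(x, 0.90, type = 7))
  xr <- x[x >= p10 & x <= p90]

  c(
    firstorder_Energy = sum(x^2),
    firstorder_TotalEnergy = prod(vm$spacing) * sum(x^2),
    firstorder_Entropy = -sum(p * log2(p)),
    firstorder_Minimum = min(x),
    firstorder_10Percentile = p10,
    firstorder_90Percentile = p90,
    firstorder_Maximum = max(x),
    firstorder_Mean = mu,
    firstorder_Median = unname(stats::median(x)),
    firstorder_InterquartileRange =
      unname(quantile(x, 0.75, type = 7) - quantile(x, 0.25, type = 7)),
    firstorder_Range = max(x) - min(x),
    firstorder_MeanAbsoluteDeviation = mean(abs(x - mu)),
    firstorder_RobustMeanAbsoluteDeviation =
      if (length(xr)) mean(abs(xr - mean(xr))) else 0,
    firstorder_RootMeanSquared = sqrt(mean(x^2)),
    firstorder_Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    firstorder_Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    firstorder_Variance = m2,
    firstorder_Uniformity = sum(p^2)
  )
}
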