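#' Names of the 107 original-image radiomics features
#'
#' Family-qualified names in extraction order: 14 shape, 18 first-order,
#' 24 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM and 5 NGTDM features.
#'
#' @return Character vector of length 107.
#' @export
radiomics_feature_names <- function() {
  c(names(.shape_stub), names(.firstorder_stub), names(.glcm_stub),
    names(.glrlm_stub), names(.glszm_stub), names(.gldm_stub),
    names(.ngtdm_stub))
}

.shape_stub <- stats::setNames(numeric(14), c(
  "shape_MeshVolume", "shape_VoxelVolume", "shape_SurfaceArea",
  "shape_SurfaceVolumeRatio", "shape_Sphericity", "shape_Maximum3DDiameter",
  "shape_Maximum2DDiameterSlice", "shape_Maximum2DDiameterColumn",
  "shape_Maximum2DDiameterRow", "shape_MajorAxisLength",
  "shape_MinorAxisLength", "shape_LeastAxisLength", "shape_Elongation",
  "shape_Flatness"))
.firstorder_stub <- stats::setNames(numeric(18), c(
  "firstorder_Energy", "firstorder_TotalEnergy", "firstorder_Entropy",
  "firstorder_Minimum", "firstorder_10Percentile", "firstorder_90Percentile",
  "firstorder_Maximum", "firstorder_Mean", "firstorder_Median",
  "firstorder_InterquartileRange", "firstorder_Range",
  "firstorder_MeanAbsoluteDeviation",
  "firstorder_RobustMeanAbsoluteDeviation", "firstorder_RootMeanSquared",
  "firstorder_Skewness", "firstorder_Kurtosis", "firstorder_Variance",
  "firstorder_Uniformity"))
.glcm_stub <- stats::setNames(numeric(24), c(
  "glcm_Autocorrelation", "glcm_JointAverage", "glcm_ClusterProminence",
  "glcm_ClusterShade", "glcm_ClusterTendency", "glcm_Contrast",
  "glcm_Correlation", "glcm_DifferenceAverage", "glcm_DifferenceEntropy",
  "glcm_DifferenceVariance", "glcm_Id", "glcm_Idm", "glcm_Idmn", "glcm_Idn",
  "glcm_Imc1", "glcm_Imc2", "glcm_InverseVariance", "glcm_JointEnergy",
  "glcm_JointEntropy", "glcm_MCC", "glcm_MaximumProbability",
  "glcm_SumAverage", "glcm_SumEntropy", "glcm_SumSquares"))
.glrlm_stub <- stats::setNames(numeric(16), c(
  "glrlm_GrayLevelNonUniformity", "glrlm_GrayLevelNonUniformityNormalized",
  "glrlm_GrayLevelVariance", "glrlm_HighGrayLevelRunEmphasis",
  "glrlm_LongRunEmphasis", "glrlm_LongRunHighGrayLevelEmphasis",
  "glrlm_LongRunLowGrayLevelEmphasis", "glrlm_LowGrayLevelRunEmphasis",
  "glrlm_RunEntropy", "glrlm_RunLengthNonUniformity",
  "glrlm_RunLengthNonUniformityNormalized", "glrlm_RunPercentage",
  "glrlm_RunVariance", "glrlm_ShortRunEmphasis",
  "glrlm_ShortRunHighGrayLevelEmphasis",
  "glrlm_ShortRunLowGrayLevelEmphasis"))
.glszm_stub <- stats::setNames(numeric(16), c(
  "glszm_GrayLevelNonUniformity", "glszm_GrayLevelNonUniformityNormalized",
  "glszm_GrayLevelVariance", "glszm_HighGrayLevelZoneEmphasis",
  "glszm_LargeAreaEmphasis", "glszm_LargeAreaHighGrayLevelEmphasis",
  "glszm_LargeAreaLowGrayLevelEmphasis", "glszm_LowGrayLevelZoneEmphasis",
  "glszm_SizeZoneNonUniformity", "glszm_SizeZoneNonUniformityNormalized",
  "glszm_SmallAreaEmphasis", "glszm_SmallAreaHighGrayLevelEmphasis",
  "glszm_SmallAreaLowGrayLevelEmphasis", "glszm_ZoneEntropy",
  "glszm_ZonePercentage", "glszm_ZoneVariance"))
.gldm_stub <- stats::setNames(numeric(14), c(
  "gldm_DependenceEntropy", "gldm_DependenceNonUniformity",
  "gldm_DependenceNonUniformityNormalized", "gldm_DependenceVariance",
  "gldm_GrayLevelNonUniformity", "gldm_GrayLevelVariance",
  "gldm_HighGrayLevelEmphasis", "gldm_LargeDependenceEmphasis",
  "gldm_LargeDependenceHighGrayLevelEmphasis",
  "gldm_LargeDependenceLowGrayLevelEmphasis", "gldm_LowGrayLevelEmphasis",
  "gldm_SmallDependenceEmphasis",
  "gldm_SmallDependenceHighGrayLevelEmphasis",
  "gldm_SmallDependenceLowGrayLevelEmphasis"))
.ngtdm_stub <- stats::setNames(numeric(5), c(
  "ngtdm_Busyness", "ngtdm_Coarseness", "ngtdm_Complexity",
  "ngtdm_Contrast", "ngtdm_Strength"))

#' Extract the full 107-feature radiomics vector
#'
#' Resamples the volume to the target spacing, discretizes the ROI with a
#' fixed bin width and computes all seven original-image feature families:
#' shape (14), first-order (18), GLCM (24), GLRLM (16), GLSZM (16),
#' GLDM (14) and NGTDM (5). The result is deterministic for a given input.
#'
#' @param vm A [rad_volume()].
#' @param target_spacing Spacing (mm) images are standardized to before
#'   extraction; `NULL` skips resampling.
#' @param bin_width Discretization bin width in HU.
#' @param sample_id Optional id stored in the output.
#' @return A one-row tibble: `sample_id` plus 107 feature columns in the
#'   order of [radiomics_feature_names()].
#' @examples
#' vm <- make_phantom(phantom_spec(lesion_kind = "textured_blob", radii = 8))
#' feats <- extract_all(vm)
#' ncol(feats) - 1L # 107
#' @export
extract_all <- function(vm, target_spacing = c(1, 1, 2), bin_width = 25,
                        sample_id = "sample_1") {
  if (!inherits(vm, "rad_volume")) abort("`vm` must be a rad_volume.")
  if (!is.null(target_spacing)) vm <- resample_volume(vm, target_spacing)
  disc <- discretize_volume(vm, bin_width)
  vals <- c(
    extract_shape(vm),
    extract_firstorder(vm, disc),
    extract_glcm(disc),
    extract_glrlm(disc),
    extract_glszm(disc),
    extract_gldm(disc),
    extract_ngtdm(disc)
  )
  expected <- radiomics_feature_names()
  stopifnot(identical(names(vals), expected))
  dplyr::bind_cols(tibble(sample_id = sample_id),
                   as_tibble(as.list(vals)))
}

#' Extract features for a list of volumes
#'
#' @param volumes A named list of [rad_volume()] objects (names become
#'   sample ids).
#' @param ... Passed to [extract_all()].
#' @return A tibble with one row per volume.
#' @export
extract_cohort <- function(volumes, ...) {
  ids <- names(volumes) %||% sprintf("sample_%d", seq_along(volumes))
  purrr::list_rbind(purrr::map2(volumes, ids,
                                function(v, id) extract_all(v, sample_id = id, ...)))
}
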