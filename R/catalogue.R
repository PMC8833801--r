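# Frozen 107-name feature catalogue (pyradiomics-style canonical names).
.FAMILY_FEATURES <- list(
  shape = c(
    "Elongation", "Flatness", "LeastAxisLength", "MajorAxisLength",
    "Maximum2DDiameterColumn", "Maximum2DDiameterRow",
    "Maximum2DDiameterSlice", "Maximum3DDiameter", "MeshVolume",
    "MinorAxisLength", "Sphericity", "SurfaceArea", "SurfaceVolumeRatio",
    "VoxelVolume"
  ),
  firstorder = c(
    "10Percentile", "90Percentile", "Energy", "Entropy",
    "InterquartileRange", "Kurtosis", "Maximum", "MeanAbsoluteDeviation",
    "Mean", "Median", "Minimum", "Range", "RobustMeanAbsoluteDeviation",
    "RootMeanSquared", "Skewness", "TotalEnergy", "Uniformity", "Variance"
  ),
  glcm = c(
    "Autocorrelation", "ClusterProminence", "ClusterShade",
    "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
    "DifferenceEntropy", "DifferenceVariance", "Id", "Idm", "Idmn", "Idn",
    "Imc1", "Imc2", "InverseVariance", "JointAverage", "JointEnergy",
    "JointEntropy", "MCC", "MaximumProbability", "SumAverage", "SumEntropy",
    "SumSquares"
  ),
  glrlm = c(
    "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
    "GrayLevelVariance", "HighGrayLevelRunEmphasis", "LongRunEmphasis",
    "LongRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
    "LowGrayLevelRunEmphasis", "RunEntropy", "RunLengthNonUniformity",
    "RunLengthNonUniformityNormalized", "RunPercentage", "RunVariance",
    "ShortRunEmphasis", "ShortRunHighGrayLevelEmphasis",
    "ShortRunLowGrayLevelEmphasis"
  ),
  glszm = c(
    "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
    "GrayLevelVariance", "HighGrayLevelZoneEmphasis", "LargeAreaEmphasis",
    "LargeAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
    "LowGrayLevelZoneEmphasis", "SizeZoneNonUniformity",
    "SizeZoneNonUniformityNormalized", "SmallAreaEmphasis",
    "SmallAreaHighGrayLevelEmphasis", "SmallAreaLowGrayLevelEmphasis",
    "ZoneEntropy", "ZonePercentage", "ZoneVariance"
  ),
  ngtdm = c("Busyness", "Coarseness", "Complexity", "Contrast", "Strength"),
  gldm = c(
    "DependenceEntropy", "DependenceNonUniformity",
    "DependenceNonUniformityNormalized", "DependenceVariance",
    "GrayLevelNonUniformity", "GrayLevelVariance", "HighGrayLevelEmphasis",
    "LargeDependenceEmphasis", "LargeDependenceHighGrayLevelEmphasis",
    "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
    "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
    "SmallDependenceLowGrayLevelEmphasis"
  )
)

#' The radiomics feature catalogue
#'
#' Returns the frozen, ordered set of 107 feature names extracted by
#' [extract_all_features()]: 14 shape, 18 first-order, 24 GLCM, 16 GLRLM,
#' 16 GLSZM, 5 NGTDM and 14 GLDM features, keyed `family_FeatureName`.
#'
#' @param family Optional family name (`"shape"`, `"firstorder"`, `"glcm"`,
#'   `"glrlm"`, `"glszm"`, `"ngtdm"`, `"gldm"`) to restrict the result to.
#' @return Character vector of canonical feature names.
#' @examples
#' length(feature_catalogue()) # 107
#' feature_catalogue("ngtdm")
#' @export
feature_catalogue <- function(family = NULL) {
  fams <- if (is.null(family)) names(.FAMILY_FEATURES) else {
    match.arg(family, names(.FAMILY_FEATURES))
  }
  unlist(lapply(fams, function(f) paste0(f, "_", .FAMILY_FEATURES[[f]])),
         use.names = FALSE)
}
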