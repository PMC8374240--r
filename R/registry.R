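#' The 93-feature registry
#'
#' Canonical list of the 93 first-order and texture features computed per
#' (channel, ROI): 18 first-order, 24 GLCM, 16 GLRLM, 16 GLSZM, 5 NGTDM and
#' 14 GLDM features, extracted from original (unfiltered) images. The set
#' reconstructs the original-image default feature set of a widely used
#' radiomics extraction tool; shape features are deliberately absent because
#' the analysis uses first-order and texture information only.
#'
#' @return A data.frame with columns `family` and `feature`; feature names
#'   follow the `<family>_<Feature>` convention, e.g. `glcm_ClusterShade`.
#' @export
#' @examples
#' reg <- feature_registry()
#' nrow(reg)        # 93
#' table(reg$family)
feature_registry <- function() {
  fam <- list(
    firstorder = c(
      "Energy", "TotalEnergy", "Entropy", "Minimum", "10Percentile",
      "90Percentile", "Maximum", "Mean", "Median", "InterquartileRange",
      "Range", "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
      "RootMeanSquared", "Skewness", "Kurtosis", "Variance", "Uniformity"),
    glcm = c(
      "Autocorrelation", "JointAverage", "ClusterProminence", "ClusterShade",
      "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
      "DifferenceEntropy", "DifferenceVariance", "JointEnergy",
      "JointEntropy", "Imc1", "Imc2", "Idm", "Idmn", "Id", "Idn",
      "InverseVariance", "MaximumProbability", "SumAverage", "SumEntropy",
      "SumSquares", "MCC"),
    glrlm = c(
      "ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
      "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
      "RunLengthNonUniformityNormalized", "RunPercentage",
      "GrayLevelVariance", "RunVariance", "RunEntropy",
      "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
      "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
      "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis"),
    glszm = c(
      "SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
      "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
      "SizeZoneNonUniformityNormalized", "ZonePercentage",
      "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
      "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
      "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
      "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis"),
    ngtdm = c("Coarseness", "Contrast", "Busyness", "Complexity", "Strength"),
    gldm = c(
      "SmallDependenceEmphasis", "LargeDependenceEmphasis",
      "GrayLevelNonUniformity", "DependenceNonUniformity",
      "DependenceNonUniformityNormalized", "GrayLevelVariance",
      "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
      "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
      "SmallDependenceHighGrayLevelEmphasis",
      "LargeDependenceLowGrayLevelEmphasis",
      "LargeDependenceHighGrayLevelEmphasis")
  )
  data.frame(
    family = rep(names(fam), lengths(fam)),
    feature = paste0(rep(names(fam), lengths(fam)), "_", unlist(fam)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' @rdname feature_registry
#' @export
feature_names <- function() feature_registry()$feature
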