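FIRST_ORDER_NAMES <- c("Mean", "Median", "Sum", "StandardDeviation", "Variance",
                       "Range", "Min", "Max", "Energy", "RootMeanSquared",
                       "Skewness", "Kurtosis", "Entropy", "Uniformity",
                       "Percentile10", "Percentile90", "InterquartileRange")

SHAPE_NAMES <- c("VoxelVolume", "SurfaceArea", "Sphericity",
                 "SurfaceToVolumeRatio", "Maximum3DDiameter",
                 "Elongation", "Flatness")

GLCM_NAMES <- c("Autocorrelation", "ClusterProminence", "ClusterShade",
                "ClusterTendency", "Contrast", "Correlation",
                "DifferenceAverage", "DifferenceEntropy", "DifferenceVariance",
                "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2", "InverseVariance",
                "JointAverage", "JointEnergy", "JointEntropy",
                "MaximumProbability", "MCC", "SumAverage", "SumEntropy",
                "SumSquares", "Dissimilarity", "SumVariance")

GLRLM_NAMES <- c("ShortRunEmphasis", "LongRunEmphasis",
                 "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                 "RunLengthNonUniformity", "RunLengthNonUniformityNormalized",
                 "RunPercentage", "GrayLevelVariance", "RunVariance",
                 "RunEntropy", "LowGrayLevelRunEmphasis",
                 "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
                 "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
                 "LongRunHighGrayLevelEmphasis")

GLCM_AGG <- c("Mean", "Std", "Min", "Max", "Range")
GLRLM_AGG <- c("Mean", "Std")
WAVELET_SUBBANDS <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")

texture_names <- function() {
  c(paste0("glcm_", rep(GLCM_NAMES, each = length(GLCM_AGG)), "_", GLCM_AGG),
    paste0("glrlm_", rep(GLRLM_NAMES, each = length(GLRLM_AGG)), "_", GLRLM_AGG))
}

#' Default radiomic feature registry
#'
#' The countable registry of the 1618 features extracted per region per
#' sequence: 17 histogram-based first-order statistics, 7 shape/volume
#' features, 162 texture features (26 GLCM descriptors aggregated over the 13
#' unique 3D directions by mean/SD/min/max/range, plus 16 GLRLM descriptors
#' aggregated by mean/SD), and 1432 wavelet features (the 17 first-order and
#' 162 texture features recomputed on each of the 8 single-level Haar
#' sub-bands; shape is computed once from the mask and not per sub-band).
#' Names follow the `group_descriptor_statistic` convention.
#'
#' @return A data.frame with columns `name`, `group`
#'   (`first_order`/`shape`/`glcm`/`glrlm`/`wavelet`) and `subband` (`NA` for
#'   spatial-domain features).
#' @export
default_registry <- function() {
  tex <- texture_names()
  base <- data.frame(
    name = c(paste0("first_order_", FIRST_ORDER_NAMES),
             paste0("shape_", SHAPE_NAMES),
             tex),
    group = c(rep("first_order", length(FIRST_ORDER_NAMES)),
              rep("shape", length(SHAPE_NAMES)),
              rep("glcm", length(GLCM_NAMES) * length(GLCM_AGG)),
              rep("glrlm", length(GLRLM_NAMES) * length(GLRLM_AGG))),
    subband = NA_character_,
    stringsAsFactors = FALSE)
  wav <- do.call(rbind, lapply(WAVELET_SUBBANDS, function(sb) {
    data.frame(
      name = paste0("wavelet_", sb, "_",
                    c(paste0("first_order_", FIRST_ORDER_NAMES), tex)),
      group = "wavelet",
      subband = sb,
      stringsAsFactors = FALSE)
  }))
  out <- rbind(base, wav)
  stopifnot(!anyDuplicated(out$name))
  out
}

#' Feature counts per registry group
#'
#' @param registry A registry data.frame from [default_registry()].
#' @return Named integer vector of counts per group plus `texture` (glcm +
#'   glrlm) and `total`.
#' @export
registry_counts <- function(registry = default_registry()) {
  tab <- table(registry$group)
  cnt <- function(g) if (g %in% names(tab)) as.integer(tab[[g]]) else 0L
  c(first_order = cnt("first_order"), shape = cnt("shape"),
    texture = cnt("glcm") + cnt("glrlm"),
    wavelet = cnt("wavelet"), total = nrow(registry))
}
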