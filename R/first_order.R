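#' Gray-level discretization configuration
#'
#' Intensities are discretized into a fixed number of equal-width bins over
#' the observed range before any histogram- or matrix-based texture feature is
#' computed; a constant region maps to level 1.
#'
#' @param n_bins Number of gray levels (default 32, minimum 2).
#' @return A `discretization_config` list.
#' @export
discretization_config <- function(n_bins = 32L) {
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L) stopf("n_bins must be at least 2")
  structure(list(mode = "fixed_bin_count", n_bins = n_bins),
            class = "discretization_config")
}

#' Discretize intensities to integer gray levels
#'
#' Equal-width binning over `[min, max]` into `n_bins` levels `1..n_bins`.
#'
#' @param values Numeric vector of intensities (finite, nonempty).
#' @param config A [discretization_config()].
#' @return Integer vector of levels in `1..n_bins`.
#' @export
discretize <- function(values, config = discretization_config()) {
  if (length(values) == 0L) stopf("cannot discretize an empty vector")
  if (any(!is.finite(values))) stopf("values must be finite")
  rng <- range(values)
  if (rng[1] == rng[2]) return(rep(1L, length(values)))
  w <- (rng[2] - rng[1]) / config$n_bins
  lev <- floor((values - rng[1]) / w) + 1L
  pmin(as.integer(lev), config$n_bins)
}

#' First-order (histogram) statistics
#'
#' The 17 first-order features: Mean, Median, Sum, StandardDeviation,
#' Variance, Range, Min, Max, Energy (sum of squared intensities),
#' RootMeanSquared, Skewness, Kurtosis (excess; 0 for a normal sample),
#' Entropy and Uniformity (computed on the discretized histogram),
#' Percentile10, Percentile90 and InterquartileRange. Standard deviation,
#' variance, skewness and kurtosis use the population denominator `n`.
#'
#' @param values Numeric vector of in-region intensities (length >= 2).
#' @param config A [discretization_config()] for Entropy/Uniformity.
#' @return Named numeric vector of length 17.
#' @export
first_order <- function(values, config = discretization_config()) {
  if (length(values) < 2L) stopf("first_order needs at least 2 voxels")
  if (any(!is.finite(values))) stopf("values must be finite")
  n <- length(values)
  m <- mean(values)
  dev <- values - m
  m2 <- mean(dev^2)
  m3 <- mean(dev^3)
  m4 <- mean(dev^4)
  lev <- discretize(values, config)
  p <- tabulate(lev, config$n_bins) / n
  p <- p[p > 0]
  q <- quantile(values, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  c(first_order_Mean = m,
    first_order_Median = median(values),
    first_order_Sum = sum(values),
    first_order_StandardDeviation = sqrt(m2),
    first_order_Variance = m2,
    first_order_Range = max(values) - min(values),
    first_order_Min = min(values),
    first_order_Max = max(values),
    first_order_Energy = sum(values^2),
    first_order_RootMeanSquared = sqrt(mean(values^2)),
    first_order_Skewness = if (m2 > 0) m3 / m2^1.5 else NaN,
    first_order_Kurtosis = if (m2 > 0) m4 / m2^2 - 3 else NaN,
    first_order_Entropy = -sum(p * log2(p)),
    first_order_Uniformity = sum(p^2),
    first_order_Percentile10 = q[1],
    first_order_Percentile90 = q[4],
    first_order_InterquartileRange = q[3] - q[2])
}
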