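# First-order intensity statistics over the ROI voxels.
# Entropy and uniformity use the fixed-bin-width discretized histogram;
# percentiles use the linear-interpolation convention (quantile type 7).
# Skewness and kurtosis of a constant ROI are defined as 0.

#' First-order radiomics features
#'
#' The 18 first-order statistics of the ROI intensity distribution.
#' `ff_energy` is the sum of squared HU values, `ff_total_energy` scales
#' it by the voxel volume; `ff_entropy` (bits) and `ff_uniformity` are
#' computed on the discretized histogram; `ff_rmad` is the mean absolute
#' deviation of values within the 10th-90th percentile band; kurtosis is
#' not excess kurtosis (a Gaussian gives about 3).
#'
#' @param x numeric vector of ROI voxel intensities (HU).
#' @param voxel_volume voxel volume in mm^3.
#' @param bin_width discretization bin width in HU.
#' @return Named numeric vector of 18 features.
#' @export
first_order_features <- function(x, voxel_volume, bin_width = 25) {
  n <- length(x)
  if (n == 0L) .stop2("rimshrink_empty_roi_error", "first-order: empty ROI")
  lev <- floor((x - min(x)) / bin_width) + 1
  p <- tabulate(lev) / n
  p <- p[p > 0]
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  q <- unname(quantile(x, c(0.10, 0.25, 0.75, 0.90), type = 7))
  band <- x[x >= q[1] & x <= q[4]]
  c(ff_energy = sum(x^2),
    ff_total_energy = voxel_volume * sum(x^2),
    ff_entropy = -sum(p * log2(p)),
    ff_minimum = min(x),
    ff_p10 = q[1],
    ff_p90 = q[4],
    ff_maximum = max(x),
    ff_mean = mu,
    ff_median = median(x),
    ff_iqr = q[3] - q[2],
    ff_range = max(x) - min(x),
    ff_mad = mean(abs(x - mu)),
    ff_rmad = if (length(band)) mean(abs(band - mean(band))) else 0,
    ff_rms = sqrt(mean(x^2)),
    ff_skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    ff_kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    ff_variance = m2,
    ff_uniformity = sum(p^2))
}
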