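#' Discretize intensities into gray levels
#'
#' Fixed-bin-width discretization: `level(v) = floor((v - min) / bin_width) + 1`,
#' so the region minimum always maps to level 1. Fixed width (rather than a
#' fixed level count) is the natural choice for calibrated CT-like units.
#'
#' @param x numeric vector or array of intensities (non-empty).
#' @param bin_width positive bin width in intensity units.
#' @return integer gray levels `>= 1`, same shape as `x`.
#' @export
discretize <- function(x, bin_width) {
  abort_if(length(x) == 0, "`x` must be non-empty")
  abort_if(!is.numeric(bin_width) || length(bin_width) != 1 || bin_width <= 0,
           "`bin_width` must be a single positive number")
  lv <- floor((x - min(x)) / bin_width) + 1
  if (is.array(x)) array(as.integer(lv), dim(x)) else as.integer(lv)
}

#' First-order intensity statistics (19 features)
#'
#' The 19 first-order features of the catalogue, computed from the raw
#' intensities inside a mask. `Entropy` and `Uniformity` are computed on the
#' fixed-bin-width discretized histogram; `Energy`/`TotalEnergy` use raw
#' intensities (total energy scales by the physical voxel volume). Skewness
#' and kurtosis use population moments, with the convention that both are 0
#' for a constant region (kurtosis is the non-excess form, 3 for a normal
#' distribution). Percentiles use linear interpolation between order
#' statistics.
#'
#' @param values numeric vector of the intensities inside the region
#'   (>= 2 values).
#' @param bin_width discretization width for `Entropy`/`Uniformity`.
#' @param voxel_volume physical voxel volume (mm^3) for `TotalEnergy`.
#' @return named numeric vector of 19 features (`firstorder_*`).
#' @export
first_order_features <- function(values, bin_width = 25, voxel_volume = 1) {
  abort_if(length(values) < 2, "first-order features need at least 2 voxels")
  n <- length(values)
  mu <- mean(values)
  m2 <- mean((values - mu)^2)          # population variance
  m3 <- mean((values - mu)^3)
  m4 <- mean((values - mu)^4)
  lv <- discretize(values, bin_width)
  p <- tabulate(lv) / n
  p <- p[p > 0]
  q <- quantile(values, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  robust <- values[values >= q[1] & values <= q[4]]
  c(firstorder_Energy = sum(values^2),
    firstorder_TotalEnergy = voxel_volume * sum(values^2),
    firstorder_Entropy = -sum(p * log2(p)),
    firstorder_Minimum = min(values),
    firstorder_10Percentile = q[1],
    firstorder_90Percentile = q[4],
    firstorder_Maximum = max(values),
    firstorder_Mean = mu,
    firstorder_Median = median(values),
    firstorder_InterquartileRange = q[3] - q[2],
    firstorder_Range = max(values) - min(values),
    firstorder_MeanAbsoluteDeviation = mean(abs(values - mu)),
    firstorder_RobustMeanAbsoluteDeviation =
      if (length(robust)) mean(abs(robust - mean(robust))) else 0,
    firstorder_RootMeanSquared = sqrt(mean(values^2)),
    firstorder_Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    firstorder_Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    firstorder_Variance = m2,
    firstorder_Uniformity = sum(p^2),
    firstorder_StandardDeviation = sqrt(m2))
}
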