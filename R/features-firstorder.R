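#' First-order intensity statistics (18 features)
#'
#' Classic histogram/intensity statistics of the masked voxels. `Entropy`
#' and `Uniformity` are computed on the discretised gray-level histogram;
#' all other features use raw (matched) intensities. Percentiles use linear
#' interpolation; `Skewness`/`Kurtosis` use population moments (kurtosis is
#' not excess-corrected and equals 3 for a Gaussian); for a constant region
#' both are reported as 0.
#'
#' @param volume An [image_volume()] or array.
#' @param mask A [segmentation_mask()] or logical array.
#' @param disc Optional [discretize()] result (recomputed if omitted).
#' @return Named numeric vector of 18 `firstorder_*` features.
#' @export
first_order_features <- function(volume, mask, disc = NULL) {
  arr <- as_volume_array(volume)
  m <- as_mask_array(mask)
  check_aligned(arr, m)
  v <- arr[m]
  n <- length(v)
  if (is.null(disc)) {
    disc <- discretize(volume, mask, choose_bin_width(volume, mask))
  }
  voxvol <- prod(volume_spacing(volume, mask))
  p <- tabulate(disc$levels[m], nbins = disc$n_bins) / n
  p <- p[p > 0]
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  qs <- quantile(v, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  robust <- v[v >= qs[1] & v <= qs[4]]
  vals <- c(
    "10Percentile" = qs[1],
    "90Percentile" = qs[4],
    Energy = sum(v^2),
    Entropy = -sum(p * log2(p)),
    InterquartileRange = qs[3] - qs[2],
    Kurtosis = if (m2 > 0) mean((v - mu)^4) / m2^2 else 0,
    Maximum = max(v),
    MeanAbsoluteDeviation = mean(abs(v - mu)),
    Mean = mu,
    Median = median(v),
    Minimum = min(v),
    Range = max(v) - min(v),
    RobustMeanAbsoluteDeviation =
      if (length(robust)) mean(abs(robust - mean(robust))) else 0,
    RootMeanSquared = sqrt(mean(v^2)),
    Skewness = if (m2 > 0) mean((v - mu)^3) / m2^1.5 else 0,
    TotalEnergy = voxvol * sum(v^2),
    Uniformity = sum(p^2),
    Variance = m2
  )
  setNames(as.numeric(vals), paste0("firstorder_", names(vals)))
}
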