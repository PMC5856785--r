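#' First-order histogram features of a VOI
#'
#' Nine intensity-histogram statistics of the in-mask voxel values: mean,
#' variance, skewness, kurtosis and the 1st/10th/50th/90th/99th
#' percentiles. The 10th percentile is the point below which 10% of the
#' voxel values forming the histogram are found (counting from the left of
#' the histogram); percentiles use linear interpolation between order
#' statistics (the convention of [stats::quantile()] type 7, frozen here).
#' Moments are population moments (divide by n); kurtosis is excess
#' kurtosis (Gaussian = 0). With a single voxel the variance is 0 and
#' skewness/kurtosis are undefined and returned as `NA`.
#'
#' @param voi a [voi()] object.
#' @return Named numeric vector of length 9: `Mean`, `Variance`,
#'   `Skewness`, `Kurtosis`, `Perc.01%`, `Perc.10%`, `Perc.50%`,
#'   `Perc.90%`, `Perc.99%`.
#' @export
#' @examples
#' v <- voi(array(rep(-500, 8), c(2, 2, 2)), array(TRUE, c(2, 2, 2)))
#' histogram_features(v)[["Mean"]]
histogram_features <- function(voi) {
  x <- voi_values(voi)
  n <- length(x)
  m <- mean(x)
  v <- mean((x - m)^2)
  if (v == 0) {
    skew <- NA_real_
    kurt <- NA_real_
  } else {
    skew <- mean((x - m)^3) / v^1.5
    kurt <- mean((x - m)^4) / v^2 - 3
  }
  p <- stats::quantile(x, probs = c(0.01, 0.10, 0.50, 0.90, 0.99),
                       names = FALSE, type = 7)
  c("Mean" = m, "Variance" = v, "Skewness" = skew, "Kurtosis" = kurt,
    "Perc.01%" = p[1], "Perc.10%" = p[2], "Perc.50%" = p[3],
    "Perc.90%" = p[4], "Perc.99%" = p[5])
}
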