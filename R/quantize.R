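#' Gray-level quantization settings
#'
#' Texture matrices are computed on intensities quantized to a small number
#' of gray levels by equal-width binning of the in-mask intensity range.
#'
#' @param n_levels number of gray levels (>= 2; default 64).
#' @return A list of class `quantization_spec`.
#' @export
quantization_spec <- function(n_levels = 64L) {
  n_levels <- as.integer(n_levels)
  if (is.na(n_levels) || n_levels < 2L) stop("n_levels must be >= 2")
  structure(list(n_levels = n_levels), class = "quantization_spec")
}

#' Quantize a VOI to integer gray levels
#'
#' Maps in-mask intensities to levels `1..n_levels` by equal-width binning
#' of `[min, max]` within the mask. A constant region maps to level 1
#' everywhere. Out-of-mask voxels are set to `NA` so downstream texture
#' counting can ignore them.
#'
#' @param voi a [voi()] object.
#' @param spec a [quantization_spec()].
#' @return 3D integer array, `NA` outside the mask.
#' @export
quantize_voi <- function(voi, spec = quantization_spec()) {
  stopifnot(inherits(voi, "voi"), inherits(spec, "quantization_spec"))
  v <- voi$image[voi$mask]
  lo <- min(v); hi <- max(v)
  q <- array(NA_integer_, dim = dim(voi$image))
  if (hi == lo) {
    q[voi$mask] <- 1L
    return(q)
  }
  lev <- pmin(floor((voi$image[voi$mask] - lo) / (hi - lo) *
                      spec$n_levels) + 1L, spec$n_levels)
  q[voi$mask] <- as.integer(lev)
  q
}
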