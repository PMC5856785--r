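# Coiflet-1 analysis filters (orthonormal; published constants).
coif1_dec_lo <- c(-0.015655728135465, -0.072732619512854, 0.384864846864203,
                  0.852572020212255, 0.337897662457809, -0.072732619512854)
coif1_dec_hi <- c(0.072732619512854, 0.337897662457809, -0.852572020212255,
                  0.384864846864203, 0.072732619512854, -0.015655728135465)

# one level of periodized 1D DWT along the columns of a matrix; n rows even
dwt_cols <- function(x, filt) {
  n <- nrow(x)
  half <- n %/% 2L
  out <- matrix(0, half, ncol(x))
  for (m in seq_along(filt)) {
    idx <- ((2L * seq_len(half) - 2L + (m - 1L)) %% n) + 1L
    out <- out + filt[m] * x[idx, , drop = FALSE]
  }
  out
}

#' One level of the 2D coiflet-1 wavelet transform
#'
#' Periodized (circular) orthonormal decomposition of a matrix with even
#' dimensions into the four subbands LL, LH, HL, HH. Because the transform
#' is orthonormal, the squared coefficients of the four subbands sum
#' exactly to the squared input samples (Parseval).
#'
#' @param x numeric matrix with even numbers of rows and columns.
#' @return List with matrices `LL`, `LH`, `HL`, `HH`, each of half size.
#' @export
coif1_dwt2 <- function(x) {
  stopifnot(is.matrix(x), nrow(x) %% 2L == 0L, ncol(x) %% 2L == 0L)
  lo <- dwt_cols(x, coif1_dec_lo)
  hi <- dwt_cols(x, coif1_dec_hi)
  # columns done; transpose to filter the second dimension
  ll <- t(dwt_cols(t(lo), coif1_dec_lo))
  lh <- t(dwt_cols(t(lo), coif1_dec_hi))
  hl <- t(dwt_cols(t(hi), coif1_dec_lo))
  hh <- t(dwt_cols(t(hi), coif1_dec_hi))
  list(LL = ll, LH = lh, HL = hl, HH = hh)
}

# 2x2 block "any" downsampling of a logical matrix (coefficient support)
downsample_support <- function(s) {
  r <- seq_len(nrow(s) %/% 2L)
  c <- seq_len(ncol(s) %/% 2L)
  s[2L * r - 1L, , drop = FALSE][, 2L * c - 1L, drop = FALSE] |
    s[2L * r - 1L, , drop = FALSE][, 2L * c, drop = FALSE] |
    s[2L * r, , drop = FALSE][, 2L * c - 1L, drop = FALSE] |
    s[2L * r, , drop = FALSE][, 2L * c, drop = FALSE]
}

#' Wavelet subband energies of a VOI
#'
#' Applies a 5-level 2D coiflet-1 wavelet decomposition to every axial
#' slice of the mask bounding box and reports the energy of each subband
#' at each scale: `WavEnLL_s-1` ... `WavEnHH_s-5`, 20 features. The
#' bounding box is padded to a multiple of 2^5 per in-plane axis,
#' out-of-mask voxels are filled with the in-mask mean, and the energy of a
#' subband is the mean squared coefficient over coefficients whose dyadic
#' block overlaps the mask, averaged over the slices that contain mask
#' voxels.
#'
#' @param voi a [voi()] object.
#' @param n_scales decomposition depth (default 5).
#' @return Named numeric vector of length `4 * n_scales`.
#' @export
wavelet_energies <- function(voi, n_scales = 5L) {
  stopifnot(inherits(voi, "voi"))
  n_scales <- as.integer(n_scales)
  mask <- voi$mask
  img <- voi$image
  fill <- mean(img[mask])

  idx <- which(mask, arr.ind = TRUE)
  rr <- range(idx[, 1]); cc <- range(idx[, 2]); zz <- range(idx[, 3])
  block <- 2L^n_scales
  pad_to <- function(len) as.integer(block * ceiling(len / block))
  nr <- pad_to(rr[2] - rr[1] + 1L)
  nc <- pad_to(cc[2] - cc[1] + 1L)

  bands <- c("LL", "LH", "HL", "HH")
  acc <- matrix(0, n_scales, 4, dimnames = list(NULL, bands))
  nsl <- 0L
  for (z in zz[1]:zz[2]) {
    msl <- mask[rr[1]:rr[2], cc[1]:cc[2], z, drop = TRUE]
    if (!is.matrix(msl))
      msl <- matrix(msl, rr[2] - rr[1] + 1L, cc[2] - cc[1] + 1L)
    if (!any(msl)) next
    nsl <- nsl + 1L
    isl <- img[rr[1]:rr[2], cc[1]:cc[2], z, drop = TRUE]
    if (!is.matrix(isl)) isl <- matrix(isl, nrow(msl), ncol(msl))
    x <- matrix(fill, nr, nc)
    x[seq_len(nrow(msl)), seq_len(ncol(msl))] <- ifelse(msl, isl, fill)
    supp <- matrix(FALSE, nr, nc)
    supp[seq_len(nrow(msl)), seq_len(ncol(msl))] <- msl
    for (s in seq_len(n_scales)) {
      sub <- coif1_dwt2(x)
      supp <- downsample_support(supp)
      w <- which(supp)
      for (b in bands)
        acc[s, b] <- acc[s, b] + mean(sub[[b]][w]^2)
      x <- sub$LL
    }
  }
  en <- as.vector(t(acc)) / nsl    # order: scale 1 LL,LH,HL,HH, scale 2 ...
  names(en) <- paste0("WavEn", rep(bands, n_scales), "_s-",
                      rep(seq_len(n_scales), each = 4))
  en
}
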