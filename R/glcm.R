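#' Gray-level co-occurrence matrix of a quantized VOI
#'
#' Counts pairs of in-mask voxels separated by the in-plane offset
#' `(d1, d2)` (rows, columns) within each axial slice, sums the counts over
#' slices, symmetrizes, and normalizes to sum 1. Out-of-mask voxels (`NA`
#' in the quantized grid) never contribute.
#'
#' @param q quantized integer 3D array as from [quantize_voi()] (or a 2D
#'   matrix, treated as a single slice).
#' @param offset integer length-2 displacement `(d1, d2)` in (row, column).
#' @param n_levels number of gray levels; defaults to `max(q)`.
#' @return `n_levels` x `n_levels` matrix summing to 1.
#' @export
glcm <- function(q, offset, n_levels = max(q, na.rm = TRUE)) {
  if (is.matrix(q)) q <- array(q, dim = c(dim(q), 1L))
  stopifnot(length(dim(q)) == 3L, length(offset) == 2L)
  d1 <- as.integer(offset[1]); d2 <- as.integer(offset[2])
  if (d1 == 0L && d2 == 0L) stop("offset must be nonzero")
  dm <- dim(q)
  counts <- numeric(n_levels * n_levels)
  r1 <- seq_len(dm[1] - abs(d1))
  c1 <- seq_len(dm[2] - abs(d2))
  if (length(r1) == 0 || length(c1) == 0)
    stop("no voxel pairs admit this offset")
  # source / destination index windows for the shifted comparison
  rs <- if (d1 >= 0) r1 else r1 + abs(d1)
  rd <- if (d1 >= 0) r1 + d1 else r1
  cs <- if (d2 >= 0) c1 else c1 + abs(d2)
  cd <- if (d2 >= 0) c1 + d2 else c1
  for (z in seq_len(dm[3])) {
    a <- q[rs, cs, z]
    b <- q[rd, cd, z]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    counts <- counts + tabulate((a[ok] - 1L) * n_levels + b[ok],
                                nbins = n_levels * n_levels)
  }
  total <- sum(counts)
  if (total == 0) stop("no in-mask voxel pairs admit this offset")
  p <- matrix(counts, n_levels, n_levels, byrow = TRUE)
  p <- p + t(p)
  p / sum(p)
}

#' Haralick-type statistics of a normalized GLCM
#'
#' Twelve co-occurrence statistics: angular second moment, contrast,
#' correlation, sum of squares (variance), inverse difference moment, sum
#' average, sum variance, sum entropy, entropy, difference variance,
#' difference entropy and dissimilarity. Entropies use the natural
#' logarithm with the convention `0 log 0 = 0`. For a constant image the
#' gray-level spread is zero and correlation is undefined; it is returned
#' as 0.
#'
#' @param p normalized symmetric co-occurrence matrix (sums to 1).
#' @return Named numeric vector of length 12.
#' @export
glcm_features <- function(p) {
  if (abs(sum(p) - 1) > 1e-8)
    stop("co-occurrence matrix must be normalized to sum 1")
  L <- nrow(p)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  px <- rowSums(p)
  mu <- sum(seq_len(L) * px)
  sig2 <- sum((seq_len(L) - mu)^2 * px)

  ent <- function(w) { w <- w[w > 0]; -sum(w * log(w)) }

  # distributions of i+j (2..2L) and |i-j| (0..L-1)
  psum <- vapply(2:(2 * L), function(k) sum(p[i + j == k]), numeric(1))
  ks <- 2:(2 * L)
  pdiff <- vapply(0:(L - 1), function(k) sum(p[abs(i - j) == k]), numeric(1))
  kd <- 0:(L - 1)

  sum_avg <- sum(ks * psum)
  sum_var <- sum((ks - sum_avg)^2 * psum)
  diff_avg <- sum(kd * pdiff)

  corr <- if (sig2 > 0) (sum(i * j * p) - mu^2) / sig2 else 0

  c(
    AngScMom = sum(p^2),
    Contrast = sum((i - j)^2 * p),
    Correlat = corr,
    SumOfSqs = sig2,
    InvDfMom = sum(p / (1 + (i - j)^2)),
    SumAverg = sum_avg,
    SumVarnc = sum_var,
    SumEntrp = ent(psum),
    Entropy  = ent(p),
    DifVarnc = sum((kd - diff_avg)^2 * pdiff),
    DifEntrp = ent(pdiff),
    Dissimlr = sum(abs(i - j) * p)
  )
}
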