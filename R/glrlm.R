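#' Gray-level run-length matrix of a quantized VOI
#'
#' Counts maximal runs of identical gray level along one in-plane direction
#' within each axial slice, summed over slices. Out-of-mask voxels (`NA`)
#' break runs and are never counted.
#'
#' @param q quantized integer 3D array (or 2D matrix = single slice).
#' @param direction one of `"0"` (horizontal), `"90"` (vertical), `"45"`,
#'   `"135"` (the two in-plane diagonals), in degrees.
#' @param n_levels number of gray levels; defaults to `max(q)`.
#' @return Numeric matrix `r` with `r[g, l]` = number of runs of gray level
#'   `g` and length `l`; `sum(l * r[, l])` equals the number of in-mask
#'   voxels (each voxel lies in exactly one run per direction).
#' @export
glrlm <- function(q, direction = c("0", "45", "90", "135"),
                  n_levels = max(q, na.rm = TRUE)) {
  direction <- match.arg(as.character(direction),
                         c("0", "45", "90", "135"))
  if (is.matrix(q)) q <- array(q, dim = c(dim(q), 1L))
  stopifnot(length(dim(q)) == 3L)
  dm <- dim(q)
  nvox <- sum(!is.na(q))
  if (nvox == 0) stop("degenerate mask: no in-mask voxels")
  max_len <- max(dm[1], dm[2])
  counts <- matrix(0, n_levels, max_len)

  for (z in seq_len(dm[3])) {
    m <- q[, , z, drop = TRUE]
    if (!is.matrix(m)) m <- matrix(m, dm[1], dm[2])
    lines <- switch(direction,
      "0"   = split(m, row(m)),
      "90"  = split(m, col(m)),
      "45"  = split(m, row(m) + col(m)),       # anti-diagonals
      "135" = split(m, col(m) - row(m)))       # main diagonals
    for (v in lines) {
      r <- rle(as.vector(v))
      keep <- !is.na(r$values)
      if (!any(keep)) next
      g <- r$values[keep]
      l <- r$lengths[keep]
      for (k in seq_along(g))
        counts[g[k], l[k]] <- counts[g[k], l[k]] + 1
    }
  }
  counts
}

#' Run-length statistics of a GLRLM
#'
#' Seven statistics of one run-length matrix: short-run emphasis, long-run
#' emphasis, gray-level non-uniformity, run-length non-uniformity, run
#' percentage (fraction of in-mask voxels that start... formally, total
#' runs divided by total voxels traversed), low gray-level run emphasis and
#' high gray-level run emphasis.
#'
#' @param r run-length matrix from [glrlm()].
#' @return Named numeric vector of length 7: `ShrtREmp`, `LngREmph`,
#'   `GLevNonU`, `RLNonUni`, `Fraction`, `LowGRE`, `HighGRE`.
#' @export
glrlm_features <- function(r) {
  R <- sum(r)
  if (R == 0) stop("empty run-length matrix")
  g <- seq_len(nrow(r))
  l <- seq_len(ncol(r))
  rg <- rowSums(r)    # runs per gray level
  rl <- colSums(r)    # runs per length
  nvox <- sum(rl * l)
  c(
    ShrtREmp = sum(sweep(r, 2, l^2, `/`)) / R,
    LngREmph = sum(sweep(r, 2, l^2, `*`)) / R,
    GLevNonU = sum(rg^2) / R,
    RLNonUni = sum(rl^2) / R,
    Fraction = R / nvox,
    LowGRE   = sum(rg / g^2) / R,
    HighGRE  = sum(rg * g^2) / R
  )
}
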