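# Marching-cubes isosurface area of a binary mask at iso-level 0.5.
# The mask is zero-padded so surfaces touching the grid edge are closed.
# Every 2x2x2 cell of voxel centers is classified by which corners lie
# inside; the frozen cell table (R/mc_table.R) gives the triangulation of
# each of the 254 mixed configurations with vertices at edge midpoints.
# Cells sharing a configuration contribute identical area, so the total is
# a weighted sum over configurations.
surface_mesh_area <- function(mask, spacing) {
  d <- dim(mask)
  f <- array(0L, dim = d + 2L)
  f[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- as.integer(mask)
  dp <- dim(f)

  n1 <- dp[1] - 1L; n2 <- dp[2] - 1L; n3 <- dp[3] - 1L
  cfg <- array(0L, dim = c(n1, n2, n3))
  b <- 0L
  for (oz in 0:1) for (oy in 0:1) for (ox in 0:1) {
    # bit b corresponds to corner (ox, oy, oz), b = ox + 2*oy + 4*oz
    bit <- 2L^(ox + 2L * oy + 4L * oz)
    cfg <- cfg + bit * f[(1 + ox):(n1 + ox),
                         (1 + oy):(n2 + oy),
                         (1 + oz):(n3 + oz)]
  }
  counts <- tabulate(cfg[cfg > 0L & cfg < 255L], nbins = 254L)
  if (sum(counts) == 0) return(0)

  lut <- mc_cell_triangles()
  area <- 0
  for (k in which(counts > 0L)) {
    tri <- lut[[k]]
    if (is.null(tri)) next
    v1 <- sweep(tri[, 1:3, drop = FALSE], 2, spacing, `*`)
    v2 <- sweep(tri[, 4:6, drop = FALSE], 2, spacing, `*`)
    v3 <- sweep(tri[, 7:9, drop = FALSE], 2, spacing, `*`)
    u <- v2 - v1; w <- v3 - v1
    cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
    cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
    cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
    area <- area + counts[k] * sum(0.5 * sqrt(cx^2 + cy^2 + cz^2))
  }
  area
}

# maximum pairwise distance between points (rows), chunked to bound memory
max_pairwise_distance <- function(p) {
  n <- nrow(p)
  if (n < 2) return(0)
  best <- 0
  chunk <- 512L
  starts <- seq(1L, n, by = chunk)
  for (s in starts) {
    rows <- s:min(s + chunk - 1L, n)
    d2 <- outer(rowSums(p[rows, , drop = FALSE]^2),
                rowSums(p^2), `+`) -
      2 * p[rows, , drop = FALSE] %*% t(p)
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}

#' Morphological (shape) features of a segmentation mask
#'
#' Eight 3D shape descriptors: the longest 3D diameter (maximum pairwise
#' Euclidean distance between surface-voxel centers, mm), volume (voxel
#' count times voxel volume, mm^3), surface area (marching-tetrahedra mesh
#' over the binary mask, mm^2), sphericity
#' `pi^(1/3) (6V)^(2/3) / A`, compactness `36 pi V^2 / A^3` (1 for a
#' sphere), elongation and flatness (square roots of the second and third
#' principal-axis eigenvalue ratios of the voxel-position covariance), and
#' the surface-to-volume ratio (1/mm). For a single-voxel mask the
#' diameter is 0 and sphericity, compactness, elongation and flatness are
#' undefined (`NA`).
#'
#' @param mask binary 3D array.
#' @param spacing mm per voxel, length 3.
#' @return Named numeric vector of length 8.
#' @export
shape_features <- function(mask, spacing = c(1, 1, 1)) {
  stopifnot(length(dim(mask)) == 3L)
  mask <- array(as.logical(mask), dim = dim(mask))
  nvox <- sum(mask)
  if (nvox == 0) stop("degenerate mask: no voxels")
  spacing <- as.numeric(spacing)
  vol <- nvox * prod(spacing)

  idx <- which(mask, arr.ind = TRUE)
  # surface voxels: at least one 6-neighbour outside the mask
  interior <- mask
  for (ax in 1:3) for (by in c(1L, -1L)) {
    n <- dim(mask)[ax]
    res <- array(FALSE, dim = dim(mask))
    if (n >= 2) {
      ii <- list(1:dim(mask)[1], 1:dim(mask)[2], 1:dim(mask)[3])
      jj <- ii
      ii[[ax]] <- if (by > 0) 2:n else 1:(n - 1)
      jj[[ax]] <- if (by > 0) 1:(n - 1) else 2:n
      res[ii[[1]], ii[[2]], ii[[3]]] <- mask[jj[[1]], jj[[2]], jj[[3]]]
    }
    interior <- interior & res
  }
  surf_idx <- which(mask & !interior, arr.ind = TRUE)
  surf_pts <- sweep(surf_idx, 2, spacing, `*`)
  diam <- max_pairwise_distance(surf_pts)

  area <- surface_mesh_area(mask, spacing)

  if (nvox >= 2) {
    pts <- sweep(idx, 2, spacing, `*`)
    cv <- stats::cov(pts)
    ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ev <- pmax(ev, 0)
    elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else NA_real_
    flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else NA_real_
    spher <- pi^(1 / 3) * (6 * vol)^(2 / 3) / area
    compact <- 36 * pi * vol^2 / area^3
  } else {
    elong <- NA_real_; flat <- NA_real_
    spher <- NA_real_; compact <- NA_real_
  }

  c(Diam3D = diam, Volume = vol, SurfArea = area, Sphericity = spher,
    Compactness = compact, Elongation = elong, Flatness = flat,
    SurfToVolRatio = area / vol)
}
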