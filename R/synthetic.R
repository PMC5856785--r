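#' Default per-class feature parameters for the synthetic cohort
#'
#' Per-class means and standard deviations of the five informative features
#' used throughout the package's examples and tests. The values are the
#' published per-class summary statistics (mean +/- SD) of the five
#' top-ranked radiomic features in the VPI-negative (stage IA) and
#' VPI-positive (stage IB) groups.
#'
#' @return A data.frame with columns `feature`, `mean_neg`, `sd_neg`,
#'   `mean_pos`, `sd_pos`.
#' @export
table2_feature_params <- function() {
  data.frame(
    feature  = c("Perc.10%", "WavEnLL_s-2", "S(0,1)SumAverg",
                 "45dgr_GLevNonU", "S(3,3)Contrast"),
    mean_neg = c(-420, 1378, 19.20, 20.73, 14.41),
    sd_neg   = c(136, 621, 10.11, 15.1, 6.36),
    mean_pos = c(-211, 3075, 30.65, 98.7, 10.01),
    sd_pos   = c(104, 522, 6.07, 40.3, 5.78),
    stringsAsFactors = FALSE
  )
}

#' Specification of a synthetic two-class feature cohort
#'
#' Describes a cases-by-features table with two classes (VPI- / VPI+):
#' a set of named informative features drawn per-class Gaussian with given
#' means/SDs, plus uninformative noise features drawn identically in both
#' classes.
#'
#' @param n_vpi_neg,n_vpi_pos cases per class (each >= 2).
#' @param feature_params data.frame as returned by [table2_feature_params()].
#' @param n_noise_features number of pure-noise features.
#' @param noise_sd standard deviation of the noise features (>= 0).
#' @param correlation optional within-class equicorrelation in [0, 1) among
#'   the informative features (0 = independent, the default).
#' @param seed integer RNG seed; a fixed seed yields an identical table.
#' @return A list of class `feature_cohort_spec`.
#' @export
feature_cohort_spec <- function(n_vpi_neg = 192, n_vpi_pos = 135,
                                feature_params = table2_feature_params(),
                                n_noise_features = 95, noise_sd = 1,
                                correlation = 0, seed = 1L) {
  if (n_vpi_neg < 2 || n_vpi_pos < 2)
    stop("need at least 2 cases per class")
  stopifnot(is.data.frame(feature_params),
            all(c("feature", "mean_neg", "sd_neg", "mean_pos", "sd_pos")
                %in% names(feature_params)))
  if (any(feature_params$sd_neg <= 0) || any(feature_params$sd_pos <= 0))
    stop("all feature standard deviations must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (correlation < 0 || correlation >= 1)
    stop("correlation must lie in [0, 1)")
  structure(
    list(n_vpi_neg = as.integer(n_vpi_neg), n_vpi_pos = as.integer(n_vpi_pos),
         feature_params = feature_params,
         n_noise_features = as.integer(n_noise_features),
         noise_sd = noise_sd, correlation = correlation,
         seed = as.integer(seed)),
    class = "feature_cohort_spec"
  )
}

#' Class labels used across the package
#' @return factor levels, negative class first.
#' @keywords internal
vpi_levels <- function() c("VPI-", "VPI+")

#' Generate a synthetic two-class feature table
#'
#' Draws each informative feature per class from a Gaussian with the
#' specified mean and SD (optionally equicorrelated within class); noise
#' features are Gaussian with mean 0 and `noise_sd` in both classes, so they
#' carry no class signal.
#'
#' @param spec a [feature_cohort_spec()].
#' @return A data.frame: `case_id`, `label` (factor `VPI-`/`VPI+`), then one
#'   column per feature.
#' @export
#' @examples
#' tab <- generate_feature_cohort(feature_cohort_spec(
#'   n_vpi_neg = 10, n_vpi_pos = 10, n_noise_features = 3, seed = 7))
#' dim(tab)
generate_feature_cohort <- function(spec) {
  stopifnot(inherits(spec, "feature_cohort_spec"))
  set.seed(spec$seed)
  fp <- spec$feature_params
  k <- nrow(fp)
  n <- c(spec$n_vpi_neg, spec$n_vpi_pos)
  rho <- spec$correlation

  draw_class <- function(nc, means, sds) {
    z <- matrix(stats::rnorm(nc * k), nc, k)
    if (rho > 0 && k > 1) {
      common <- stats::rnorm(nc)
      z <- sqrt(rho) * common + sqrt(1 - rho) * z
    }
    sweep(sweep(z, 2, sds, `*`), 2, means, `+`)
  }

  xneg <- draw_class(n[1], fp$mean_neg, fp$sd_neg)
  xpos <- draw_class(n[2], fp$mean_pos, fp$sd_pos)
  x <- rbind(xneg, xpos)
  colnames(x) <- fp$feature

  if (spec$n_noise_features > 0) {
    noise <- matrix(stats::rnorm(sum(n) * spec$n_noise_features,
                                 sd = spec$noise_sd),
                    sum(n), spec$n_noise_features)
    colnames(noise) <- sprintf("noise%03d", seq_len(spec$n_noise_features))
    x <- cbind(x, noise)
  }

  out <- data.frame(
    case_id = sprintf("case%04d", seq_len(sum(n))),
    label = factor(rep(vpi_levels(), n), levels = vpi_levels()),
    stringsAsFactors = FALSE,
    check.names = FALSE
  )
  cbind(out, as.data.frame(x, check.names = FALSE))
}

#' Specification of a synthetic 3D nodule image cohort
#'
#' Two classes of ellipsoidal nodule phantoms embedded in a lung-like
#' background. The classes can differ in mean nodule attenuation
#' (`class_intensity_shift`, HU added to class 2) and in texture, realised
#' as Gaussian-smoothed noise whose correlation length differs per class.
#'
#' @param n_per_class phantoms per class.
#' @param grid_shape integer length-3 grid extent in voxels.
#' @param spacing mm per voxel (length 3).
#' @param nodule_radius_range min/max nodule radius in mm.
#' @param class_intensity_shift HU added to the nodule interior of class 2.
#' @param class_texture_scale length-2 correlation length (mm) of the
#'   smoothed noise field, one per class.
#' @param texture_sd HU standard deviation of the texture field.
#' @param base_intensity mean nodule attenuation (HU) of class 1.
#' @param background_intensity mean attenuation of surrounding lung (HU).
#' @param seed integer RNG seed.
#' @return A list of class `image_cohort_spec`.
#' @export
image_cohort_spec <- function(n_per_class = 25,
                              grid_shape = c(40, 40, 24),
                              spacing = c(0.7, 0.7, 1.0),
                              nodule_radius_range = c(5, 9),
                              class_intensity_shift = 150,
                              class_texture_scale = c(1.0, 2.5),
                              texture_sd = 80,
                              base_intensity = -350,
                              background_intensity = -850,
                              seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  spacing <- as.numeric(spacing)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8L),
            length(spacing) == 3L, all(spacing > 0),
            length(nodule_radius_range) == 2L,
            nodule_radius_range[1] > 0,
            nodule_radius_range[1] <= nodule_radius_range[2],
            length(class_texture_scale) == 2L,
            all(class_texture_scale > 0))
  half_extent <- grid_shape * spacing / 2
  if (nodule_radius_range[2] >= min(half_extent) - max(spacing))
    stop("nodule does not fit inside the grid")
  structure(
    list(n_per_class = as.integer(n_per_class), grid_shape = grid_shape,
         spacing = spacing, nodule_radius_range = nodule_radius_range,
         class_intensity_shift = class_intensity_shift,
         class_texture_scale = class_texture_scale,
         texture_sd = texture_sd, base_intensity = base_intensity,
         background_intensity = background_intensity,
         seed = as.integer(seed)),
    class = "image_cohort_spec"
  )
}

# separable Gaussian smoothing of a 3D field; sigma in voxels per axis
smooth_field_3d <- function(x, sigma) {
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s < 1e-3) next
    half <- max(1L, ceiling(3 * s))
    kern <- stats::dnorm(seq(-half, half), sd = s)
    kern <- kern / sum(kern)
    x <- aperm(apply(aperm(x, c(ax, setdiff(1:3, ax))), 2:3,
      function(v) {
        n <- length(v)
        vp <- c(rev(v[seq_len(half)]), v, rev(v[n - seq_len(half) + 1]))
        stats::convolve(vp, rev(kern), type = "filter")
      }),
      order(c(ax, setdiff(1:3, ax))))
  }
  x
}

#' Generate a synthetic 3D nodule image cohort
#'
#' Each case is an ellipsoidal nodule (random radius within
#' `nodule_radius_range`, mild random anisotropy) on a noisy lung
#' background; the mask is the ellipsoid. Class 2 nodules are shifted by
#' `class_intensity_shift` HU and textured with a different correlation
#' length, so intensity and texture features genuinely differ between
#' classes when the respective parameters differ, and do not when they are
#' equal.
#'
#' @param spec an [image_cohort_spec()].
#' @return A list with elements `vois` (list of [voi()]) and `labels`
#'   (factor, `VPI-`/`VPI+`, balanced).
#' @export
generate_image_cohort <- function(spec) {
  stopifnot(inherits(spec, "image_cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_per_class
  labels <- factor(rep(vpi_levels(), each = n), levels = vpi_levels())
  dims <- spec$grid_shape
  centre <- (dims + 1) / 2
  coords <- list(
    (seq_len(dims[1]) - centre[1]) * spec$spacing[1],
    (seq_len(dims[2]) - centre[2]) * spec$spacing[2],
    (seq_len(dims[3]) - centre[3]) * spec$spacing[3]
  )

  vois <- vector("list", 2L * n)
  for (i in seq_len(2L * n)) {
    cls <- if (i <= n) 1L else 2L
    r0 <- stats::runif(1, spec$nodule_radius_range[1],
                       spec$nodule_radius_range[2])
    semi <- r0 * stats::runif(3, 0.85, 1.15)
    semi <- pmin(semi, dims * spec$spacing / 2 - spec$spacing)
    d2 <- outer(outer((coords[[1]] / semi[1])^2,
                      (coords[[2]] / semi[2])^2, `+`),
                (coords[[3]] / semi[3])^2, `+`)
    mask <- d2 <= 1

    sigma_vox <- spec$class_texture_scale[cls] / spec$spacing
    tex <- smooth_field_3d(array(stats::rnorm(prod(dims)), dim = dims),
                           sigma_vox)
    tex <- tex / stats::sd(tex) * spec$texture_sd

    img <- array(spec$background_intensity +
                   stats::rnorm(prod(dims), sd = 25), dim = dims)
    shift <- if (cls == 2L) spec$class_intensity_shift else 0
    img[mask] <- spec$base_intensity + shift + tex[mask]

    vois[[i]] <- voi(img, mask, spacing = spec$spacing,
                     case_id = sprintf("img%04d", i))
  }
  list(vois = vois, labels = labels)
}

#' Specification of a re-segmentation perturbation
#'
#' Emulates a second reader's independent segmentation of the same lesion:
#' the mask boundary is dilated (`boundary_shift` > 0) or eroded
#' (`boundary_shift` < 0) by that many voxels, and Gaussian noise is added
#' to the intensities. Feature values from the original and the perturbed
#' VOI form the replicate pairs used by the reproducibility (CCC) filter.
#'
#' @param boundary_shift signed integer, voxels of dilation/erosion.
#' @param intensity_noise_sd HU noise standard deviation (>= 0).
#' @param seed integer RNG seed.
#' @return A list of class `perturbation_spec`.
#' @export
perturbation_spec <- function(boundary_shift = 1L, intensity_noise_sd = 10,
                              seed = 1L) {
  stopifnot(intensity_noise_sd >= 0)
  structure(
    list(boundary_shift = as.integer(boundary_shift),
         intensity_noise_sd = intensity_noise_sd, seed = as.integer(seed)),
    class = "perturbation_spec"
  )
}

# one step of 6-connected binary dilation / erosion
morph_step <- function(mask, dilate = TRUE) {
  d <- dim(mask)
  out <- mask
  shifted <- function(ax, by) {
    # voxels beyond the grid count as background for both operations
    res <- array(FALSE, dim = d)
    n <- d[ax]
    from <- if (by > 0) 1:(n - 1) else 2:n
    to <- if (by > 0) 2:n else 1:(n - 1)
    ii <- list(1:d[1], 1:d[2], 1:d[3])
    jj <- ii
    ii[[ax]] <- to; jj[[ax]] <- from
    res[ii[[1]], ii[[2]], ii[[3]]] <- mask[jj[[1]], jj[[2]], jj[[3]]]
    res
  }
  for (ax in 1:3) for (by in c(1L, -1L)) {
    s <- shifted(ax, by)
    out <- if (dilate) out | s else out & s
  }
  out
}

#' Perturb a VOI's segmentation to emulate a second reader
#'
#' @param voi a [voi()] object.
#' @param spec a [perturbation_spec()].
#' @return A new [voi()] with the shifted mask and noisy intensities,
#'   carrying the same `case_id` so replicates stay paired.
#' @export
perturb_segmentation <- function(voi, spec) {
  stopifnot(inherits(voi, "voi"), inherits(spec, "perturbation_spec"))
  set.seed(spec$seed)
  mask <- voi$mask
  k <- abs(spec$boundary_shift)
  if (k > 0) {
    for (i in seq_len(k))
      mask <- morph_step(mask, dilate = spec$boundary_shift > 0)
    if (!any(mask))
      stop("degenerate mask: erosion removed every voxel")
  }
  img <- voi$image
  if (spec$intensity_noise_sd > 0)
    img <- img + array(stats::rnorm(length(img),
                                    sd = spec$intensity_noise_sd),
                       dim = dim(img))
  voi(img, mask, spacing = voi$spacing, case_id = voi$case_id)
}
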