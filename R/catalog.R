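glcm_stat_names <- c("AngScMom", "Contrast", "Correlat", "SumOfSqs",
                     "InvDfMom", "SumAverg", "SumVarnc", "SumEntrp",
                     "Entropy", "DifVarnc", "DifEntrp", "Dissimlr")
glrlm_stat_names <- c("ShrtREmp", "LngREmph", "GLevNonU", "RLNonUni",
                      "Fraction", "LowGRE", "HighGRE")
glrlm_dir_prefix <- c("0" = "Horzl_", "90" = "Vertl_",
                      "45" = "45dgr_", "135" = "135dr_")

# in-plane GLCM offsets: 4 directions x 5 distances, (row, column)
glcm_offsets <- function(distances = 1:5) {
  out <- list()
  for (d in distances)
    out <- c(out, list(c(0L, d), c(d, 0L), c(d, d), c(d, -d)))
  out
}

shape_feature_names <- c("Diam3D", "Volume", "SurfArea", "Sphericity",
                         "Compactness", "Elongation", "Flatness",
                         "SurfToVolRatio")
histogram_feature_names <- c("Mean", "Variance", "Skewness", "Kurtosis",
                             "Perc.01%", "Perc.10%", "Perc.50%",
                             "Perc.90%", "Perc.99%")

#' The 308-feature radiomic catalog
#'
#' The default feature catalog: 8 shape + 9 histogram + 271 texture
#' (12 co-occurrence statistics for 20 in-plane offsets
#' `(0,d), (d,0), (d,d), (d,-d)`, `d = 1..5`, giving 240; 7 run-length
#' statistics for 4 in-plane directions plus 3 direction-pooled
#' aggregates, giving 31) + 20 wavelet subband energies (4 subbands x
#' 5 scales). Feature names follow the MaZda-style labels used in the
#' clinical radiomics literature (`S(0,1)SumAverg`, `45dgr_GLevNonU`,
#' `WavEnLL_s-2`, `Perc.10%`).
#'
#' @return A data.frame with columns `name` and `group`
#'   (`shape`/`histogram`/`texture`/`wavelet`), 308 rows, names unique.
#' @export
feature_catalog <- function() {
  glcm_names <- unlist(lapply(glcm_offsets(), function(o)
    sprintf("S(%d,%d)%s", o[1], o[2], glcm_stat_names)))
  glrlm_names <- c(
    unlist(lapply(glrlm_dir_prefix, function(p)
      paste0(p, glrlm_stat_names)), use.names = FALSE),
    paste0("All_", c("GLevNonU", "RLNonUni", "Fraction")))
  wav_names <- paste0("WavEn", rep(c("LL", "LH", "HL", "HH"), 5), "_s-",
                      rep(1:5, each = 4))
  data.frame(
    name = c(shape_feature_names, histogram_feature_names,
             glcm_names, glrlm_names, wav_names),
    group = c(rep("shape", length(shape_feature_names)),
              rep("histogram", length(histogram_feature_names)),
              rep("texture", length(glcm_names) + length(glrlm_names)),
              rep("wavelet", length(wav_names))),
    stringsAsFactors = FALSE
  )
}

#' Extract the full 308-feature vector from a VOI
#'
#' Computes every feature of [feature_catalog()] on one volume of
#' interest. Texture features are computed on the gray-level-quantized
#' grid (equal-width binning within the mask, [quantize_voi()]). Features
#' whose preconditions fail on a degenerate VOI (for example co-occurrence
#' offsets admitting no voxel pair in a single-voxel mask) are returned as
#' `NA` rather than aborting the extraction.
#'
#' @param voi a [voi()] object.
#' @param quantization a [quantization_spec()].
#' @return Named numeric vector of length 308, in catalog order.
#' @export
#' @examples
#' set.seed(1)
#' img <- array(rnorm(16 * 16 * 4, -500, 80), c(16, 16, 4))
#' msk <- array(TRUE, c(16, 16, 4))
#' fv <- extract_features(voi(img, msk))
#' length(fv)
extract_features <- function(voi, quantization = quantization_spec()) {
  stopifnot(inherits(voi, "voi"))
  cat_names <- feature_catalog()$name

  safe <- function(expr, template) {
    tryCatch(expr, error = function(e) {
      out <- rep(NA_real_, length(template))
      names(out) <- template
      out
    })
  }

  sh <- safe(shape_features(voi$mask, voi$spacing), shape_feature_names)
  hi <- safe(histogram_features(voi), histogram_feature_names)

  q <- quantize_voi(voi, quantization)
  L <- quantization$n_levels

  gl <- unlist(lapply(glcm_offsets(), function(o) {
    stats <- safe(glcm_features(glcm(q, o, n_levels = L)), glcm_stat_names)
    names(stats) <- sprintf("S(%d,%d)%s", o[1], o[2], names(stats))
    stats
  }))

  run_mats <- lapply(names(glrlm_dir_prefix), function(dir)
    glrlm(q, dir, n_levels = L))
  names(run_mats) <- names(glrlm_dir_prefix)
  rl <- unlist(lapply(names(run_mats), function(dir) {
    stats <- safe(glrlm_features(run_mats[[dir]]), glrlm_stat_names)
    names(stats) <- paste0(glrlm_dir_prefix[[dir]], names(stats))
    stats
  }))
  # pooled over the four directions
  maxlen <- max(vapply(run_mats, ncol, integer(1)))
  pooled <- matrix(0, L, maxlen)
  for (r in run_mats)
    pooled[, seq_len(ncol(r))] <- pooled[, seq_len(ncol(r))] + r
  pf <- safe(glrlm_features(pooled), glrlm_stat_names)
  rl <- c(rl, "All_GLevNonU" = unname(pf["GLevNonU"]),
          "All_RLNonUni" = unname(pf["RLNonUni"]),
          "All_Fraction" = unname(pf["Fraction"]))

  wv <- safe(wavelet_energies(voi), paste0(
    "WavEn", rep(c("LL", "LH", "HL", "HH"), 5), "_s-", rep(1:5, each = 4)))

  out <- c(sh, hi, gl, rl, wv)
  stopifnot(identical(names(out), cat_names))
  out
}

#' Extract features for a list of VOIs into a feature table
#'
#' @param vois list of [voi()] objects.
#' @param labels optional factor/vector of class labels, one per VOI.
#' @param quantization a [quantization_spec()].
#' @return A data.frame: `case_id`, optional `label`, then one column per
#'   catalog feature.
#' @export
extract_cohort <- function(vois, labels = NULL,
                           quantization = quantization_spec()) {
  feats <- t(vapply(vois, extract_features, numeric(308),
                    quantization = quantization))
  out <- data.frame(
    case_id = vapply(vois, function(v) v$case_id, character(1)),
    stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(labels)) out$label <- labels
  cbind(out, as.data.frame(feats, check.names = FALSE))
}
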