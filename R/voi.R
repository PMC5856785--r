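#' Volume of interest (VOI)
#'
#' A VOI bundles a 3D intensity grid in Hounsfield units (HU), an aligned
#' binary segmentation mask, and the physical voxel spacing in millimetres.
#' It is the unit on which all radiomic features are computed.
#'
#' @param image 3D numeric array of intensities (HU).
#' @param mask 3D array (logical or 0/1) of the same dimensions as `image`.
#' @param spacing numeric length-3 vector, mm per voxel along each axis.
#' @param case_id optional identifier carried through feature tables.
#'
#' @return An object of class `voi`: a list with elements `image`, `mask`
#'   (logical array), `spacing` and `case_id`.
#' @export
#' @examples
#' img <- array(rnorm(4^3, -500, 50), dim = c(4, 4, 4))
#' msk <- array(TRUE, dim = c(4, 4, 4))
#' v <- voi(img, msk, spacing = c(1, 1, 1))
voi <- function(image, mask, spacing = c(1, 1, 1), case_id = NA_character_) {
  if (!is.array(image) || length(dim(image)) != 3L)
    stop("`image` must be a 3D array")
  if (!identical(dim(image), dim(mask)))
    stop("`image` and `mask` must have identical dimensions")
  mask <- array(as.logical(mask), dim = dim(mask))
  if (anyNA(mask)) stop("`mask` must not contain NA")
  if (!any(mask)) stop("degenerate mask: no voxels selected")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive numbers (mm)")
  structure(
    list(image = image, mask = mask, spacing = spacing,
         case_id = as.character(case_id)),
    class = "voi"
  )
}

#' @export
print.voi <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<voi> %s  grid %dx%dx%d  spacing %.2fx%.2fx%.2f mm  %d mask voxels\n",
              x$case_id, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3], sum(x$mask)))
  invisible(x)
}

#' Masked intensity values of a VOI
#' @param voi a [voi()] object.
#' @return numeric vector of in-mask intensities.
#' @export
voi_values <- function(voi) {
  stopifnot(inherits(voi, "voi"))
  voi$image[voi$mask]
}

#' Read a VOI from NIfTI volume and mask files
#'
#' @param image_path path to the intensity volume (`.nii` / `.nii.gz`).
#' @param mask_path path to the aligned binary mask.
#' @param case_id optional case identifier (defaults to the image file name).
#' @return A [voi()] object; spacing is taken from the image header.
#' @export
read_voi <- function(image_path, mask_path, case_id = NULL) {
  img <- RNifti::readNifti(image_path)
  msk <- RNifti::readNifti(mask_path)
  sp <- RNifti::pixdim(img)[1:3]
  if (is.null(case_id))
    case_id <- sub("\\.nii(\\.gz)?$", "", basename(image_path))
  voi(array(as.numeric(img), dim = dim(img)[1:3]),
      array(as.numeric(msk) > 0.5, dim = dim(msk)[1:3]),
      spacing = sp, case_id = case_id)
}

#' Write a VOI as a NIfTI volume + mask pair
#'
#' @param voi a [voi()] object.
#' @param image_path,mask_path output paths (`.nii.gz` recommended).
#' @return Invisibly, the two paths.
#' @export
write_voi <- function(voi, image_path, mask_path) {
  stopifnot(inherits(voi, "voi"))
  img <- RNifti::asNifti(voi$image)
  RNifti::pixdim(img) <- voi$spacing
  msk <- RNifti::asNifti(array(as.integer(voi$mask), dim = dim(voi$mask)))
  RNifti::pixdim(msk) <- voi$spacing
  RNifti::writeNifti(img, image_path)
  RNifti::writeNifti(msk, mask_path)
  invisible(c(image_path, mask_path))
}
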