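#' 3D scalar volume with physical geometry
#'
#' A `volume_image` is a plain 3D array of intensities (Hounsfield units for
#' CT) together with the voxel spacing and the world-coordinate position of
#' the first voxel centre. Axis order is (x, y, z): the first array index
#' moves fastest along the patient x axis, matching the NIfTI on-disk layout.
#'
#' @param values numeric 3D array of intensities.
#' @param spacing numeric length-3 vector of voxel edge lengths in mm, all
#'   strictly positive.
#' @param origin numeric length-3 vector, world coordinate (mm) of the centre
#'   of voxel (1, 1, 1).
#' @return An object of class `volume_image` with elements `values`,
#'   `spacing`, `origin`.
#' @examples
#' img <- volume_image(array(rnorm(27), c(3, 3, 3)), spacing = c(1, 1, 1))
#' dim(img$values)
#' @export
volume_image <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (!all(is.finite(values)))
    stop("`values` must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive numbers")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image> %s voxels, spacing %s mm, origin %s mm\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' Read a volume or mask from NIfTI
#'
#' Reads a NIfTI file into a [volume_image]. Voxel spacing is taken from the
#' header `pixdim`; the origin is the world position of the first voxel as
#' given by the sform/qform. Use `read_mask()` for label images: it
#' additionally binarizes (> 0) and returns a logical array plus geometry.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [volume_image].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop("cannot read volume: file not found: ", path)
  nii <- RNifti::readNifti(path)
  if (length(dim(nii)) != 3L)
    stop("expected a 3D NIfTI volume: ", path)
  vals <- array(as.numeric(nii), dim = dim(nii)) # strip header attributes
  xf <- RNifti::xform(nii)
  # xform maps 0-based voxel indices to world mm; the offset column is the
  # world position of the first voxel centre and the column norms the spacing
  spacing <- sqrt(colSums(xf[1:3, 1:3]^2))
  if (any(spacing <= 0)) spacing <- abs(RNifti::pixdim(nii)[1:3])
  origin <- as.numeric(xf[1:3, 4])
  volume_image(vals, spacing = spacing, origin = origin)
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  img <- read_volume(path)
  img$values <- array(img$values > 0, dim = dim(img$values))
  img
}

#' Write a volume or binary mask to NIfTI
#'
#' Masks are stored as unsigned 8-bit with 0/1 coding; intensity volumes as
#' 32-bit float. The affine is diagonal in the voxel spacing with the stored
#' origin (no implicit axis flips).
#'
#' @param img a [volume_image] (for `write_mask`, its `values` may be logical
#'   or 0/1 numeric).
#' @param path output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_volume <- function(img, path) {
  stopifnot(inherits(img, "volume_image"))
  aff <- diag(4)
  aff[1, 1] <- img$spacing[1]
  aff[2, 2] <- img$spacing[2]
  aff[3, 3] <- img$spacing[3]
  aff[1:3, 4] <- img$origin
  vals <- img$values
  storage.mode(vals) <- "double"
  nii <- RNifti::asNifti(vals, datatype = "double")
  RNifti::sform(nii) <- structure(aff, code = 2L)
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
write_mask <- function(img, path) {
  stopifnot(inherits(img, "volume_image") || is.array(img))
  if (is.array(img)) img <- volume_image(img * 1)
  vals <- array(as.integer(img$values != 0), dim = dim(img$values))
  aff <- diag(4)
  aff[1, 1] <- img$spacing[1]
  aff[2, 2] <- img$spacing[2]
  aff[3, 3] <- img$spacing[3]
  aff[1:3, 4] <- img$origin
  nii <- RNifti::asNifti(vals, datatype = "uint8")
  RNifti::sform(nii) <- structure(aff, code = 2L)
  RNifti::writeNifti(nii, path)
  invisible(path)
}
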