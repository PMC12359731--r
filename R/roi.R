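#' Spacing-aware Euclidean dilation of a binary mask
#'
#' Grows a binary mask outward by a physical margin: a voxel belongs to the
#' dilated mask iff its centre lies within Euclidean distance `margin_mm` (in
#' mm, using the voxel spacing) of some foreground voxel centre. Implemented
#' with an exact Euclidean distance transform, so anisotropic spacing is
#' handled correctly and the margin is not quantized to whole structuring
#' elements.
#'
#' @param mask logical (or 0/1) 3D array.
#' @param spacing_mm numeric length-3 voxel spacing in mm.
#' @param margin_mm dilation margin in mm, > 0.
#' @return Logical 3D array of the same dimensions.
#' @export
dilate_mask <- function(mask, spacing_mm, margin_mm) {
  mask <- array(mask != 0, dim = dim(mask))
  if (!any(mask)) stop("cannot dilate an empty mask")
  if (!is.numeric(margin_mm) || length(margin_mm) != 1L || margin_mm <= 0)
    stop("`margin_mm` must be a single positive number")
  spacing_mm <- as.numeric(spacing_mm)
  stopifnot(length(spacing_mm) == 3L, all(spacing_mm > 0))
  d2 <- cpp_edt_sq(mask, dim(mask), spacing_mm)
  array(d2 <= margin_mm^2, dim = dim(mask))
}

#' GTV / GPTV / GPR region-of-interest triplet
#'
#' From a gross tumor volume (GTV) mask, builds the gross peritumoral tumor
#' volume (GPTV) by dilating the GTV outward by `margin_mm` (default 5 mm),
#' and the gross peritumoral region (GPR) as the shell GPTV minus GTV. If the
#' dilation would reach the edge of the grid the arrays are padded first (the
#' caller should pad the matching image with background, see
#' [pad_volume()]); a warning reports the padding.
#'
#' @param gtv_mask logical (or 0/1) 3D array, nonempty.
#' @param spacing_mm numeric length-3 voxel spacing in mm.
#' @param margin_mm peritumoral margin in mm (default 5).
#' @param restrict_mask optional logical array on the same grid (e.g. a lung
#'   segmentation): peritumoral voxels outside it are removed from GPTV and
#'   GPR. The default (`NULL`) is unrestricted Euclidean dilation.
#' @return An object of class `roi_triplet`: list with logical arrays `gtv`,
#'   `gptv`, `gpr`, the `margin_mm`, and `pad` (voxels of zero-padding added
#'   per axis, 0 if none).
#' @export
build_roi_triplet <- function(gtv_mask, spacing_mm, margin_mm = 5,
                              restrict_mask = NULL) {
  gtv <- array(gtv_mask != 0, dim = dim(gtv_mask))
  if (!any(gtv)) stop("GTV mask is empty")
  spacing_mm <- as.numeric(spacing_mm)
  need <- ceiling(margin_mm / spacing_mm) + 1L
  idx <- which(gtv, arr.ind = TRUE)
  lo <- apply(idx, 2, min)
  hi <- apply(idx, 2, max)
  pad <- pmax(0L, as.integer(pmax(need - (lo - 1L), need - (dim(gtv) - hi))))
  if (any(pad > 0L)) {
    warning("GTV margin reaches the grid boundary; padding by (",
            paste(pad, collapse = ", "), ") voxels per side")
    gtv <- pad_array(gtv, pad, FALSE)
  }
  gptv <- dilate_mask(gtv, spacing_mm, margin_mm)
  if (!is.null(restrict_mask)) {
    restrict <- array(restrict_mask != 0, dim = dim(restrict_mask))
    if (any(pad > 0L)) restrict <- pad_array(restrict, pad, FALSE)
    gptv <- (gptv & restrict) | gtv
  }
  gpr <- gptv & !gtv
  structure(list(gtv = gtv, gptv = gptv, gpr = gpr,
                 margin_mm = margin_mm, pad = pad),
            class = "roi_triplet")
}

#' @export
print.roi_triplet <- function(x, ...) {
  cat(sprintf(
    "<roi_triplet> margin %.1f mm; voxels GTV %d, GPTV %d, GPR %d\n",
    x$margin_mm, sum(x$gtv), sum(x$gptv), sum(x$gpr)))
  invisible(x)
}

#' Pad a 3D array symmetrically
#'
#' @param a 3D array.
#' @param pad integer length-3, voxels added on both ends of each axis.
#' @param fill fill value (e.g. -1024 for CT background, FALSE for masks).
#' @return The padded array.
#' @export
pad_array <- function(a, pad, fill) {
  pad <- as.integer(pad)
  d <- dim(a) + 2L * pad
  out <- array(fill, dim = d)
  out[pad[1] + seq_len(dim(a)[1]),
      pad[2] + seq_len(dim(a)[2]),
      pad[3] + seq_len(dim(a)[3])] <- a
  out
}

#' @rdname pad_array
#' @param img a [volume_image]; the origin is shifted so world coordinates of
#'   the original voxels are preserved.
#' @export
pad_volume <- function(img, pad, fill = -1024) {
  stopifnot(inherits(img, "volume_image"))
  volume_image(pad_array(img$values, pad, fill),
               spacing = img$spacing,
               origin = img$origin - as.integer(pad) * img$spacing)
}

#' Largest 6-connected component of a mask
#'
#' @param mask logical 3D array.
#' @return Logical array keeping only the largest 6-connected component.
#' @export
largest_component <- function(mask) {
  mask <- array(mask != 0, dim = dim(mask))
  if (!any(mask)) return(mask)
  lab <- cpp_label6(mask, dim(mask))
  tab <- tabulate(lab[lab > 0])
  array(lab == which.max(tab), dim = dim(mask))
}

#' Number of 6-connected components
#' @param mask logical 3D array.
#' @return Integer count.
#' @export
n_components <- function(mask) {
  mask <- array(mask != 0, dim = dim(mask))
  if (!any(mask)) return(0L)
  max(cpp_label6(mask, dim(mask)))
}

#' Maximum caliper diameter of a mask
#'
#' Maximum pairwise Euclidean distance between surface-voxel centres, plus
#' optionally the mean voxel extent to account for the half-voxel the surface
#' voxels occupy beyond their centres.
#'
#' @param mask logical 3D array.
#' @param spacing_mm voxel spacing in mm.
#' @param include_extent add `mean(spacing_mm)` for the voxel extent
#'   (default FALSE: centre-to-centre distance).
#' @return Diameter in mm (0 for a single voxel with `include_extent =
#'   FALSE`).
#' @export
mask_max_diameter <- function(mask, spacing_mm, include_extent = FALSE) {
  mask <- array(mask != 0, dim = dim(mask))
  if (!any(mask)) stop("empty mask")
  surf <- mask_surface(mask)
  idx <- which(surf, arr.ind = TRUE)
  pts <- sweep(idx, 2, as.numeric(spacing_mm), `*`)
  d <- if (nrow(pts) == 1L) 0 else max(stats::dist(pts))
  if (include_extent) d <- d + mean(as.numeric(spacing_mm))
  d
}

#' Surface voxels of a mask (those with a 6-neighbour outside)
#' @param mask logical 3D array.
#' @return Logical array marking surface voxels.
#' @export
mask_surface <- function(mask) {
  mask <- array(mask != 0, dim = dim(mask))
  d <- dim(mask)
  shifted_all_in <- array(TRUE, dim = d)
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    nb <- shift_array(mask, ax, s, fill = FALSE)
    shifted_all_in <- shifted_all_in & nb
  }
  mask & !shifted_all_in
}

# shift a 3D array by s along axis ax, filling vacated cells
shift_array <- function(a, ax, s, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, dim = d)
  src <- dst <- lapply(d, seq_len)
  if (s > 0) {
    dst[[ax]] <- (1 + s):d[ax]
    src[[ax]] <- 1:(d[ax] - s)
  } else if (s < 0) {
    dst[[ax]] <- 1:(d[ax] + s)
    src[[ax]] <- (1 - s):d[ax]
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Emulate a second rater by perturbing a segmentation boundary
#'
#' Randomly adds background voxels adjacent to the mask surface and removes
#' mask surface voxels (independent coin flips at `rate`), then keeps the
#' largest 6-connected component. This models the inter-reader boundary
#' disagreement that the intraclass-correlation stability filter is designed
#' to absorb.
#'
#' @param mask logical 3D array, nonempty.
#' @param rate per-voxel perturbation probability (default 0.2).
#' @param seed integer seed for reproducibility.
#' @return Perturbed logical mask (guaranteed nonempty).
#' @export
perturb_mask <- function(mask, rate = 0.2, seed = 1L) {
  mask <- array(mask != 0, dim = dim(mask))
  if (!any(mask)) stop("empty mask")
  out <- with_seed(seed, {
    m <- mask
    surf <- mask_surface(m)
    outer_ring <- dilate_mask(m, c(1, 1, 1), 1) & !m
    add <- outer_ring & array(stats::runif(length(m)) < rate, dim = dim(m))
    drop <- surf & array(stats::runif(length(m)) < rate, dim = dim(m))
    m2 <- (m | add) & !drop
    if (!any(m2)) m else largest_component(m2)
  })
  out
}
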