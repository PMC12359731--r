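#' Wavelet and Laplacian-of-Gaussian filter bank
#'
#' `wavelet_subbands()` computes the eight sub-bands of a single-level
#' undecimated 3D Haar decomposition: each axis is filtered with either the
#' low-pass `(1, 1)/sqrt(2)` or high-pass `(1, -1)/sqrt(2)` pair (replicated
#' edges), giving LLL ... HHH at the original resolution.
#'
#' `log_filter()` convolves with the analytic Laplacian-of-Gaussian kernel,
#' assembled from three separable passes (`G''GG + GG''G + GGG''`) of the
#' sampled 1D Gaussian and its second derivative, truncated at 4 sigma. The
#' impulse response is therefore the sampled analytic LoG.
#'
#' @param img a [volume_image].
#' @return For `wavelet_subbands`, a named list of eight [volume_image]s
#'   (`LLL`, `HLL`, ..., `HHH`); for `log_filter`, one [volume_image].
#' @export
wavelet_subbands <- function(img) {
  stopifnot(inherits(img, "volume_image"))
  lo <- c(1, 1) / sqrt(2)
  hi <- c(1, -1) / sqrt(2)
  out <- list()
  for (cx in c("L", "H")) for (cy in c("L", "H")) for (cz in c("L", "H")) {
    a <- img$values
    a <- conv_axis2(a, if (cx == "L") lo else hi, 1)
    a <- conv_axis2(a, if (cy == "L") lo else hi, 2)
    a <- conv_axis2(a, if (cz == "L") lo else hi, 3)
    out[[paste0(cx, cy, cz)]] <- volume_image(a, img$spacing, img$origin)
  }
  out
}

# Two-tap filter along an axis with replicated trailing edge.
conv_axis2 <- function(a, k, ax) {
  nxt <- shift_array_rep(a, ax)
  k[1] * a + k[2] * nxt
}

# shift forward by one along axis ax, replicating the final slice
shift_array_rep <- function(a, ax) {
  d <- dim(a)
  idx <- lapply(d, seq_len)
  idx[[ax]] <- c(2:d[ax], d[ax])
  a[idx[[1]], idx[[2]], idx[[3]]]
}

#' @rdname wavelet_subbands
#' @param sigma LoG scale in mm, > 0.
#' @export
log_filter <- function(img, sigma) {
  stopifnot(inherits(img, "volume_image"))
  if (sigma <= 0) stop("`sigma` must be > 0")
  a <- img$values
  out <- array(0, dim(a))
  for (ax2 in 1:3) {
    b <- a
    for (ax in 1:3) {
      s_vox <- sigma / img$spacing[ax]
      r <- max(1L, ceiling(4 * s_vox))
      t <- seq(-r, r)
      g <- stats::dnorm(t, sd = s_vox)
      g <- g / sum(g)
      gpp <- ((t^2 - s_vox^2) / s_vox^4) * stats::dnorm(t, sd = s_vox)
      k <- if (ax == ax2) gpp else g
      b <- conv_axis(b, k, ax, renormalize = FALSE)
    }
    out <- out + b
  }
  volume_image(out, img$spacing, img$origin)
}

#' Extract all configured features for one ROI
#'
#' Shape features are computed from the mask geometry; first-order features
#' from the (optionally window-normalized) intensities inside the mask;
#' texture families from the min-anchored fixed-bin-width discretization of
#' the raw intensities inside the mask. When filters are enabled, the
#' first-order and texture families are recomputed on each derived image
#' (discretized with the same bin width) and prefixed with the filter name.
#'
#' @param img a [volume_image] holding intensities (HU for CT).
#' @param mask logical (or 0/1) 3D array on the same grid, nonempty.
#' @param prep a [preprocess_config] (bin width, window).
#' @param cfg a [feature_config].
#' @return Named numeric vector; names are `<image>_<family>_<Feature>`,
#'   e.g. `original_glcm_Contrast`.
#' @export
extract_features <- function(img, mask, prep = preprocess_config(),
                             cfg = feature_config()) {
  stopifnot(inherits(img, "volume_image"))
  mask <- array(mask != 0, dim = dim(mask))
  if (!any(mask)) stop("empty ROI mask")
  if (!identical(dim(img$values), dim(mask)))
    stop("image and mask dimensions differ")
  out <- numeric(0)
  if ("shape" %in% cfg$families) {
    sf <- shape_features(mask, img$spacing)
    names(sf) <- paste0("original_shape_", names(sf))
    out <- c(out, sf)
  }
  images <- list(original = img)
  if ("wavelet" %in% cfg$filters) {
    wb <- wavelet_subbands(img)
    names(wb) <- paste0("wavelet.", names(wb))
    images <- c(images, wb)
  }
  if ("log" %in% cfg$filters) {
    for (s in cfg$log_sigmas)
      images[[sprintf("log.sigma.%g", s)]] <- log_filter(img, s)
  }
  for (nm in names(images)) {
    vals <- images[[nm]]$values
    x <- vals[mask]
    lv <- levels_array(vals, mask, prep$bin_width)
    ng <- max(lv)
    if ("firstorder" %in% cfg$families) {
      xf <- x
      if (nm == "original" && prep$normalize_first_order)
        xf <- (x - prep$window_level) / prep$window_width
      fo <- first_order_features(xf, levels = lv[mask])
      names(fo) <- paste0(nm, "_firstorder_", names(fo))
      out <- c(out, fo)
    }
    for (fam in intersect(cfg$families,
                          c("glcm", "glrlm", "glszm", "gldm", "ngtdm"))) {
      fv <- switch(fam,
        glcm = glcm_features(lv, ng, cfg$glcm_distance),
        glrlm = glrlm_features(lv, ng),
        glszm = glszm_features(lv, ng),
        gldm = gldm_features(lv, ng, cfg$gldm_alpha),
        ngtdm = ngtdm_features(lv, ng))
      names(fv) <- paste0(nm, "_", fam, "_", names(fv))
      out <- c(out, fv)
    }
  }
  if (any(!is.finite(out)))
    stop("non-finite feature values: ",
         paste(names(out)[!is.finite(out)], collapse = ", "))
  out
}

#' Extract features for the GTV / GPTV / GPR triplet
#'
#' Each region's shape features come from its own mask and its intensity and
#' texture features from the discretized intensities within that mask.
#'
#' @param img a [volume_image].
#' @param triplet an `roi_triplet` from [build_roi_triplet()]; if the
#'   triplet was padded, the image is padded with -1024 HU to match.
#' @param prep a [preprocess_config].
#' @param cfg a [feature_config].
#' @return Named list of three named numeric vectors (`GTV`, `GPTV`, `GPR`).
#' @export
extract_all <- function(img, triplet, prep = preprocess_config(),
                        cfg = feature_config()) {
  stopifnot(inherits(triplet, "roi_triplet"))
  if (!any(triplet$gpr)) stop("GPR is empty; margin too small for this grid")
  if (any(triplet$pad > 0L)) img <- pad_volume(img, triplet$pad, fill = -1024)
  list(GTV = extract_features(img, triplet$gtv, prep, cfg),
       GPTV = extract_features(img, triplet$gptv, prep, cfg),
       GPR = extract_features(img, triplet$gpr, prep, cfg))
}

#' Number of features produced by a configuration
#'
#' `shape_n + (1 + n_derived) * sum(non-shape family sizes)` where
#' `n_derived` is 8 for the wavelet bank plus one per LoG sigma.
#'
#' @param cfg a [feature_config].
#' @return Integer feature count per ROI.
#' @export
feature_count <- function(cfg = feature_config()) {
  sizes <- c(firstorder = 17L, glcm = 20L, glrlm = 16L, glszm = 16L,
             gldm = 14L, ngtdm = 5L)
  nonshape <- sum(sizes[intersect(cfg$families, names(sizes))])
  nder <- 0L
  if ("wavelet" %in% cfg$filters) nder <- nder + 8L
  if ("log" %in% cfg$filters) nder <- nder + length(cfg$log_sigmas)
  shape_n <- if ("shape" %in% cfg$families) 10L else 0L
  as.integer(shape_n + (1L + nder) * nonshape)
}
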