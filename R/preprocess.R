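#' Preprocessing configuration
#'
#' Defaults follow the standard lung-window protocol for CT radiomics of
#' pulmonary nodules: intensities are window-normalized by subtracting the
#' window level (-600 HU) and dividing by the window width (1500 HU), images
#' are resampled to 1 mm isotropic voxels with cubic B-spline interpolation
#' (nearest neighbour for masks), and gray levels are discretized with a
#' fixed bin width of 25 HU.
#'
#' Discretization operates on the original HU values inside each ROI, not on
#' the window-normalized values: a 25-HU bin on intensities rescaled to a
#' unit range would collapse every ROI to a single gray level. Normalization
#' is applied (by default) only to the intensities feeding the first-order
#' statistics.
#'
#' @param window_level window level in HU (default -600).
#' @param window_width window width in HU (default 1500), > 0.
#' @param target_spacing_mm length-3 resampling target (default 1,1,1 mm).
#' @param bin_width gray-level bin width in HU (default 25), > 0.
#' @param normalize_first_order apply window normalization to the
#'   intensities used for first-order features (default TRUE).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(window_level = -600, window_width = 1500,
                              target_spacing_mm = c(1, 1, 1),
                              bin_width = 25,
                              normalize_first_order = TRUE) {
  if (window_width <= 0) stop("`window_width` must be > 0")
  if (bin_width <= 0) stop("`bin_width` must be > 0")
  target_spacing_mm <- as.numeric(target_spacing_mm)
  if (length(target_spacing_mm) != 3L ||
      any(!is.finite(target_spacing_mm)) || any(target_spacing_mm <= 0))
    stop("`target_spacing_mm` must be 3 positive numbers")
  structure(list(window_level = window_level, window_width = window_width,
                 target_spacing_mm = target_spacing_mm, bin_width = bin_width,
                 normalize_first_order = normalize_first_order),
            class = "preprocess_config")
}

#' Window-normalize CT intensities
#'
#' Affine intensity map `(x - window_level) / window_width`; geometry is
#' unchanged. With the default lung window, -600 HU maps to 0 and the
#' displayed window spans \[-0.5, 0.5\].
#'
#' @param img a [volume_image].
#' @param cfg a [preprocess_config].
#' @return A [volume_image] with normalized intensities.
#' @export
normalize_intensity <- function(img, cfg = preprocess_config()) {
  stopifnot(inherits(img, "volume_image"))
  if (cfg$window_width == 0) stop("window width must be nonzero")
  volume_image((img$values - cfg$window_level) / cfg$window_width,
               spacing = img$spacing, origin = img$origin)
}

#' Resample a volume to a target spacing
#'
#' Cubic B-spline interpolation (with the exact recursive prefilter, so the
#' interpolant passes through the input samples and reproduces polynomials up
#' to degree 3). The output grid is anchored at the input origin and covers
#' the input bounding box. Boundaries use mirror extension.
#'
#' `resample_mask()` uses nearest-neighbour interpolation and returns a
#' logical array wrapped in a [volume_image], so masks stay binary.
#'
#' @param img a [volume_image].
#' @param cfg a [preprocess_config]; `cfg$target_spacing_mm` is the target.
#' @return A [volume_image] on the target grid.
#' @export
resample_volume <- function(img, cfg = preprocess_config()) {
  stopifnot(inherits(img, "volume_image"))
  tsp <- cfg$target_spacing_mm
  if (any(!is.finite(tsp)) || any(tsp <= 0)) stop("degenerate target spacing")
  if (isTRUE(all.equal(img$spacing, tsp))) return(img)
  d <- dim(img$values)
  nout <- pmax(2L, as.integer(floor((d - 1) * img$spacing / tsp)) + 1L)
  coef <- bspline_prefilter(img$values)
  out <- coef
  for (ax in 1:3) {
    u <- (seq_len(nout[ax]) - 1) * tsp[ax] / img$spacing[ax] # 0-based index
    W <- bspline_weights(u, d[ax])
    out <- apply_axis_matrix(out, W, ax)
  }
  volume_image(out, spacing = tsp, origin = img$origin)
}

#' @rdname resample_volume
#' @export
resample_mask <- function(img, cfg = preprocess_config()) {
  stopifnot(inherits(img, "volume_image"))
  tsp <- cfg$target_spacing_mm
  if (any(!is.finite(tsp)) || any(tsp <= 0)) stop("degenerate target spacing")
  vals <- array(img$values != 0, dim = dim(img$values))
  if (isTRUE(all.equal(img$spacing, tsp)))
    return(volume_image(vals * 1, img$spacing, img$origin))
  d <- dim(vals)
  nout <- pmax(2L, as.integer(floor((d - 1) * img$spacing / tsp)) + 1L)
  out <- vals * 1
  for (ax in 1:3) {
    u <- (seq_len(nout[ax]) - 1) * tsp[ax] / img$spacing[ax]
    idx <- pmin(pmax(round(u) + 1, 1), d[ax])
    W <- matrix(0, length(idx), d[ax])
    W[cbind(seq_along(idx), idx)] <- 1
    out <- apply_axis_matrix(out, W, ax)
  }
  volume_image((out > 0.5) * 1, spacing = tsp, origin = img$origin)
}

# Apply matrix W (n_out x n_in) along axis ax of 3D array a.
apply_axis_matrix <- function(a, W, ax) {
  d <- dim(a)
  perm <- c(ax, setdiff(1:3, ax))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = d[ax])
  res <- W %*% m
  dimo <- c(nrow(W), d[perm][2:3])
  aperm(array(res, dim = dimo), order(perm))
}

# Exact cubic B-spline prefilter (recursive causal/anticausal filtering with
# pole sqrt(3)-2, mirror boundary), applied along each axis.
bspline_prefilter <- function(a) {
  z <- sqrt(3) - 2
  for (ax in 1:3) {
    d <- dim(a)
    perm <- c(ax, setdiff(1:3, ax))
    ap <- aperm(a, perm)
    m <- matrix(ap, nrow = d[ax])
    m <- bspline_prefilter_1d(m, z)
    a <- aperm(array(m, dim = d[perm]), order(perm))
  }
  a
}

# columns of m are independent signals
bspline_prefilter_1d <- function(m, z) {
  n <- nrow(m)
  if (n == 1L) return(m)
  gain <- (1 - z) * (1 - 1 / z)
  m <- m * gain
  # causal init: mirror-symmetric sum, truncated at machine precision
  horizon <- min(n, ceiling(log(.Machine$double.eps) / log(abs(z))))
  zp <- z^(seq_len(horizon) - 1)
  cplus <- m
  cplus[1, ] <- as.numeric(zp %*% m[seq_len(horizon), , drop = FALSE])
  for (i in 2:n) cplus[i, ] <- m[i, ] + z * cplus[i - 1, ]
  cminus <- cplus
  cminus[n, ] <- (z / (z * z - 1)) * (cplus[n, ] + z * cplus[n - 1, ])
  for (i in (n - 1):1) cminus[i, ] <- z * (cminus[i + 1, ] - cplus[i, ])
  cminus
}

# Row-sparse matrix of cubic B-spline basis weights evaluating at 0-based
# positions u over a signal of length n (mirror boundary for out-of-range
# support indices).
bspline_weights <- function(u, n) {
  W <- matrix(0, length(u), n)
  b3 <- function(t) {
    t <- abs(t)
    ifelse(t < 1, (4 - 6 * t^2 + 3 * t^3) / 6,
           ifelse(t < 2, (2 - t)^3 / 6, 0))
  }
  for (r in seq_along(u)) {
    i0 <- floor(u[r])
    for (mm in (i0 - 1):(i0 + 2)) {
      w <- b3(u[r] - mm)
      if (w == 0) next
      j <- mirror_index(mm, n)
      W[r, j] <- W[r, j] + w
    }
  }
  W
}

# reflect a 0-based index into 0..n-1 (mirror without repeating the edge),
# returned 1-based
mirror_index <- function(i, n) {
  if (n == 1L) return(1L)
  p <- 2L * (n - 1L)
  i <- ((i %% p) + p) %% p
  if (i >= n) i <- p - i
  i + 1L
}

#' Fixed-bin-width gray-level discretization
#'
#' Maps intensities to integer gray levels `floor((x - min(x)) / bin_width)
#' + 1`. Levels are anchored at the ROI minimum, so a global intensity shift
#' leaves the level map unchanged, and run from 1 to
#' `floor(range / bin_width) + 1`.
#'
#' @param x numeric vector of ROI intensities (nonempty).
#' @param bin_width bin width in intensity units, > 0.
#' @return Integer vector of gray levels, with attribute `n_levels`.
#' @export
discretize_gray_levels <- function(x, bin_width = 25) {
  if (length(x) == 0L) stop("empty ROI sample")
  if (!is.numeric(bin_width) || bin_width <= 0) stop("`bin_width` must be > 0")
  lv <- as.integer(floor((x - min(x)) / bin_width)) + 1L
  attr(lv, "n_levels") <- max(lv)
  lv
}
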