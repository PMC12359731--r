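#' Feature extraction configuration
#'
#' Controls which feature families and derived (filtered) images are
#' computed. The default configuration computes the seven families
#' (first-order, shape, GLCM, GLRLM, GLSZM, GLDM, NGTDM) on the original
#' image only; enabling the wavelet and Laplacian-of-Gaussian filter bank
#' multiplies the non-shape feature count by one per derived image (8
#' wavelet sub-bands plus one per LoG sigma).
#'
#' @param families character vector of families to compute.
#' @param filters subset of `c("wavelet", "log")`; empty by default.
#' @param log_sigmas numeric vector of LoG scales in mm (all > 0).
#' @param glcm_distance co-occurrence offset in voxels (default 1).
#' @param gldm_alpha dependence similarity tolerance in gray levels
#'   (default 0).
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(families = c("firstorder", "shape", "glcm",
                                        "glrlm", "glszm", "gldm", "ngtdm"),
                           filters = character(),
                           log_sigmas = c(1, 2),
                           glcm_distance = 1,
                           gldm_alpha = 0) {
  known <- c("firstorder", "shape", "glcm", "glrlm", "glszm", "gldm", "ngtdm")
  if (!all(families %in% known))
    stop("unknown families: ", paste(setdiff(families, known), collapse = ", "))
  if (!all(filters %in% c("wavelet", "log")))
    stop("filters must be a subset of c('wavelet', 'log')")
  if (any(log_sigmas <= 0)) stop("LoG sigmas must be > 0")
  structure(list(families = families, filters = filters,
                 log_sigmas = log_sigmas, glcm_distance = glcm_distance,
                 gldm_alpha = gldm_alpha),
            class = "feature_config")
}

entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' First-order intensity statistics
#'
#' Moments, percentiles and histogram statistics of the ROI intensities.
#' Entropy and uniformity are computed on the fixed-bin-width discretized
#' histogram (log base 2); all other statistics use the raw intensities.
#' Variance, skewness and kurtosis are population moments; kurtosis is not
#' excess-corrected (a normal sample gives about 3). Constant ROIs give
#' variance 0, entropy 0, uniformity 1; skewness and kurtosis are defined as
#' 0 when the standard deviation is 0.
#'
#' @param x numeric vector of ROI intensities (nonempty).
#' @param levels integer gray levels from [discretize_gray_levels()]; if
#'   `NULL`, computed from `x` with `bin_width`.
#' @param bin_width bin width used when `levels` is NULL.
#' @return Named numeric vector of 17 features.
#' @export
first_order_features <- function(x, levels = NULL, bin_width = 25) {
  if (length(x) == 0L) stop("empty ROI")
  if (is.null(levels)) levels <- discretize_gray_levels(x, bin_width)
  n <- length(x)
  m <- mean(x)
  v <- sum((x - m)^2) / n
  s <- sqrt(v)
  p <- tabulate(levels) / n
  q <- stats::quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE,
                       type = 7)
  core <- x[x >= q[1] & x <= q[5]]
  c(Mean = m,
    Median = q[3],
    Variance = v,
    Skewness = if (s > 0) sum((x - m)^3) / n / s^3 else 0,
    Kurtosis = if (s > 0) sum((x - m)^4) / n / s^4 else 0,
    Energy = sum(x^2),
    Entropy = entropy2(p),
    Minimum = min(x),
    Maximum = max(x),
    Range = max(x) - min(x),
    Percentile10 = q[1],
    Percentile90 = q[5],
    InterquartileRange = q[4] - q[2],
    MeanAbsoluteDeviation = mean(abs(x - m)),
    RobustMeanAbsoluteDeviation = mean(abs(core - mean(core))),
    RootMeanSquared = sqrt(mean(x^2)),
    Uniformity = sum(p^2))
}

#' Shape features of a binary mask
#'
#' Volume is voxel-counting volume; surface area comes from a marching-
#' tetrahedra mesh of the lightly anti-aliased mask (Gaussian sigma 0.55
#' voxels, iso-level 0.5), using a symmetric 24-tetrahedra cell
#' decomposition. Maximum 3D diameter is the largest pairwise distance
#' between surface-voxel centres. Axis lengths derive from the principal
#' components of the voxel-centre coordinates.
#'
#' @param mask logical (or 0/1) 3D array, nonempty.
#' @param spacing numeric length-3 voxel spacing in mm.
#' @return Named numeric vector of 10 features.
#' @export
shape_features <- function(mask, spacing) {
  mask <- array(mask != 0, dim = dim(mask))
  if (!any(mask)) stop("empty mask")
  spacing <- as.numeric(spacing)
  n <- sum(mask)
  vol <- n * prod(spacing)
  # pad so the mesh closes at the grid boundary
  mpad <- pad_array(mask, c(2L, 2L, 2L), FALSE)
  f <- smooth3d(mpad * 1, 0.55)
  area <- cpp_mt_area(f, dim(f), spacing, 0.5)
  if (area <= 0) { # sub-resolution object: fall back to voxel-face area
    area <- voxel_face_area(mask, spacing)
  }
  diam <- mask_max_diameter(mask, spacing)
  idx <- which(mask, arr.ind = TRUE)
  pts <- sweep(idx, 2, spacing, `*`)
  ev <- if (n > 1) {
    eig <- eigen(stats::cov(pts), symmetric = TRUE, only.values = TRUE)$values
    pmax(eig, 0)
  } else c(0, 0, 0)
  c(VoxelVolume = vol,
    SurfaceArea = area,
    SurfaceVolumeRatio = area / vol,
    Sphericity = (36 * pi * vol^2)^(1 / 3) / area,
    Maximum3DDiameter = diam,
    MajorAxisLength = 4 * sqrt(ev[1]),
    MinorAxisLength = 4 * sqrt(ev[2]),
    LeastAxisLength = 4 * sqrt(ev[3]),
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1)
}

voxel_face_area <- function(mask, spacing) {
  a <- 0
  face <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
            spacing[1] * spacing[2])
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    nb <- shift_array(mask, ax, s, fill = FALSE)
    a <- a + sum(mask & !nb) * face[ax]
  }
  a
}

# Build a levels array: integer gray levels inside the mask, 0 outside.
levels_array <- function(values, mask, bin_width = 25) {
  mask <- array(mask != 0, dim = dim(mask))
  lv <- array(0L, dim = dim(mask))
  lv[mask] <- discretize_gray_levels(values[mask], bin_width)
  lv
}

glcm_degenerate <- function() {
  c(Autocorrelation = 0, JointAverage = 0, ClusterProminence = 0,
    ClusterShade = 0, ClusterTendency = 0, Contrast = 0, Correlation = 1,
    DifferenceAverage = 0, DifferenceEntropy = 0, DifferenceVariance = 0,
    JointEnergy = 1, JointEntropy = 0, Imc1 = 0, Imc2 = 0, Idm = 1, Id = 1,
    InverseVariance = 0, MaximumProbability = 1, SumAverage = 0,
    SumEntropy = 0)
}

#' Gray-level co-occurrence matrix features
#'
#' Co-occurrence counts are accumulated for the 13 unique 3D directions at
#' the configured voxel distance, symmetrized (`P + t(P)`), normalized, and
#' features are averaged over directions with at least one voxel pair.
#' A single-voxel ROI (no pairs in any direction) returns the constant-image
#' convention: contrast-type features 0, correlation 1, joint energy 1.
#'
#' @param levels integer 3D array of gray levels, 0 outside the ROI.
#' @param n_levels number of gray levels N_g.
#' @param distance co-occurrence offset in voxels.
#' @return Named numeric vector of 20 features.
#' @export
glcm_features <- function(levels, n_levels, distance = 1) {
  counts <- cpp_glcm(levels, dim(levels), n_levels, as.integer(distance))
  per_dir <- vector("list", 13)
  for (d in 1:13) {
    C <- matrix(counts[, , d], n_levels, n_levels)
    P <- C + t(C)
    tot <- sum(P)
    if (tot == 0) next
    per_dir[[d]] <- glcm_features_one(P / tot)
  }
  per_dir <- per_dir[!vapply(per_dir, is.null, logical(1))]
  if (length(per_dir) == 0L) return(glcm_degenerate())
  Reduce(`+`, per_dir) / length(per_dir)
}

glcm_features_one <- function(p) {
  ng <- nrow(p)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(p)
  mu <- sum(px * seq_len(ng))      # symmetric: mu_x = mu_y
  sig2 <- sum(px * (seq_len(ng) - mu)^2)
  k_diff <- 0:(ng - 1)
  pd <- vapply(k_diff, function(k) sum(p[abs(i - j) == k]), numeric(1))
  k_sum <- 2:(2 * ng)
  ps <- vapply(k_sum, function(k) sum(p[(i + j) == k]), numeric(1))
  da <- sum(k_diff * pd)
  hx <- entropy2(px)
  hxy <- entropy2(p)
  pxpy <- outer(px, px)
  nz <- p > 0 & pxpy > 0
  hxy1 <- -sum(p[nz] * log2(pxpy[nz]))
  hxy2 <- entropy2(pxpy)
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))
  offd <- i != j
  c(Autocorrelation = sum(p * i * j),
    JointAverage = sum(p * i),
    ClusterProminence = sum(p * (i + j - 2 * mu)^4),
    ClusterShade = sum(p * (i + j - 2 * mu)^3),
    ClusterTendency = sum(p * (i + j - 2 * mu)^2),
    Contrast = sum(p * (i - j)^2),
    Correlation = if (sig2 > 0) (sum(p * i * j) - mu^2) / sig2 else 1,
    DifferenceAverage = da,
    DifferenceEntropy = entropy2(pd),
    DifferenceVariance = sum(pd * (k_diff - da)^2),
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    Imc1 = imc1,
    Imc2 = imc2,
    Idm = sum(p / (1 + (i - j)^2)),
    Id = sum(p / (1 + abs(i - j))),
    InverseVariance = sum(p[offd] / (i[offd] - j[offd])^2),
    MaximumProbability = max(p),
    SumAverage = sum(k_sum * ps),
    SumEntropy = entropy2(ps))
}

#' Gray-level run-length matrix features
#'
#' Runs of identical gray level are counted along each of the 13 unique 3D
#' directions; features are computed per direction and averaged.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 features.
#' @export
glrlm_features <- function(levels, n_levels) {
  counts <- cpp_glrlm(levels, dim(levels), n_levels)
  L <- dim(counts)[2]
  feats <- vector("list", 13)
  for (d in 1:13) {
    R <- matrix(counts[, , d], n_levels, L)
    if (sum(R) == 0) next
    feats[[d]] <- rlm_szm_features(R, prefix = "run")
  }
  feats <- feats[!vapply(feats, is.null, logical(1))]
  Reduce(`+`, feats) / length(feats)
}

# Shared emphasis/nonuniformity formulas for run-length (rows = gray level,
# cols = run length) and size-zone (cols = zone size) matrices.
rlm_szm_features <- function(M, prefix = c("run", "zone")) {
  prefix <- match.arg(prefix)
  ng <- nrow(M)
  L <- ncol(M)
  i <- matrix(seq_len(ng), ng, L)
  j <- matrix(seq_len(L), ng, L, byrow = TRUE)
  Nr <- sum(M)
  Np <- sum(M * j)
  p <- M / Nr
  mu_i <- sum(p * i)
  mu_j <- sum(p * j)
  base <- c(
    ShortEmphasis = sum(M / j^2) / Nr,
    LongEmphasis = sum(M * j^2) / Nr,
    GrayLevelNonUniformity = sum(rowSums(M)^2) / Nr,
    GrayLevelNonUniformityNormalized = sum(rowSums(M)^2) / Nr^2,
    LengthNonUniformity = sum(colSums(M)^2) / Nr,
    LengthNonUniformityNormalized = sum(colSums(M)^2) / Nr^2,
    Percentage = Nr / Np,
    GrayLevelVariance = sum(p * (i - mu_i)^2),
    LengthVariance = sum(p * (j - mu_j)^2),
    Entropy = entropy2(p),
    LowGrayLevelEmphasis = sum(M / i^2) / Nr,
    HighGrayLevelEmphasis = sum(M * i^2) / Nr,
    ShortLowGrayLevelEmphasis = sum(M / (i^2 * j^2)) / Nr,
    ShortHighGrayLevelEmphasis = sum(M * i^2 / j^2) / Nr,
    LongLowGrayLevelEmphasis = sum(M * j^2 / i^2) / Nr,
    LongHighGrayLevelEmphasis = sum(M * (i * j)^2) / Nr)
  names(base) <- switch(prefix,
    run = c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
            "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
            "RunLengthNonUniformityNormalized", "RunPercentage",
            "GrayLevelVariance", "RunVariance", "RunEntropy",
            "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
            "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
            "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis"),
    zone = c("SmallAreaEmphasis", "LargeAreaEmphasis",
             "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
             "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
             "ZonePercentage", "GrayLevelVariance", "ZoneVariance",
             "ZoneEntropy", "LowGrayLevelZoneEmphasis",
             "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
             "SmallAreaHighGrayLevelEmphasis",
             "LargeAreaLowGrayLevelEmphasis",
             "LargeAreaHighGrayLevelEmphasis"))
  base
}

#' Gray-level size-zone matrix features
#'
#' Zones are 26-connected components of identical gray level; the zone
#' matrix is direction-free.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 features.
#' @export
glszm_features <- function(levels, n_levels) {
  zones <- cpp_glszm_zones(levels, dim(levels))
  if (nrow(zones) == 0L) stop("empty ROI")
  maxsize <- max(zones[, 2])
  S <- matrix(0, n_levels, maxsize)
  for (k in seq_len(nrow(zones)))
    S[zones[k, 1], zones[k, 2]] <- S[zones[k, 1], zones[k, 2]] + 1
  rlm_szm_features(S, prefix = "zone")
}

#' Gray-level dependence matrix features
#'
#' The dependence of a voxel is the number of its 26-neighbours inside the
#' ROI whose gray level differs by at most `alpha` (default 0). The
#' dependence size index includes the centre voxel, so it runs from 1 to 27
#' and the small-dependence emphasis is well defined for isolated voxels.
#'
#' @inheritParams glcm_features
#' @param alpha dependence similarity tolerance in gray levels.
#' @return Named numeric vector of 14 features.
#' @export
gldm_features <- function(levels, n_levels, alpha = 0) {
  D0 <- cpp_gldm(levels, dim(levels), as.integer(alpha))
  ng <- n_levels
  D <- matrix(0, ng, 27)
  D[seq_len(nrow(D0)), ] <- D0
  nd <- ncol(D)
  i <- matrix(seq_len(ng), ng, nd)
  j <- matrix(seq_len(nd), ng, nd, byrow = TRUE) # dependence size = dep + 1
  Nz <- sum(D)
  p <- D / Nz
  mu_i <- sum(p * i)
  mu_j <- sum(p * j)
  c(SmallDependenceEmphasis = sum(D / j^2) / Nz,
    LargeDependenceEmphasis = sum(D * j^2) / Nz,
    GrayLevelNonUniformity = sum(rowSums(D)^2) / Nz,
    DependenceNonUniformity = sum(colSums(D)^2) / Nz,
    DependenceNonUniformityNormalized = sum(colSums(D)^2) / Nz^2,
    GrayLevelVariance = sum(p * (i - mu_i)^2),
    DependenceVariance = sum(p * (j - mu_j)^2),
    DependenceEntropy = entropy2(p),
    LowGrayLevelEmphasis = sum(D / i^2) / Nz,
    HighGrayLevelEmphasis = sum(D * i^2) / Nz,
    SmallDependenceLowGrayLevelEmphasis = sum(D / (i^2 * j^2)) / Nz,
    SmallDependenceHighGrayLevelEmphasis = sum(D * i^2 / j^2) / Nz,
    LargeDependenceLowGrayLevelEmphasis = sum(D * j^2 / i^2) / Nz,
    LargeDependenceHighGrayLevelEmphasis = sum(D * (i * j)^2) / Nz)
}

#' Neighbouring gray-tone difference matrix features
#'
#' For each ROI voxel the absolute difference between its level and the mean
#' level of its in-ROI 26-neighbours is accumulated per level (edge voxels
#' use the neighbours available). A single-level ROI has contrast 0; an ROI
#' with zero total difference (perfectly smooth) has coarseness capped at
#' 1e6, following the common convention for the degenerate reciprocal.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 5 features.
#' @export
ngtdm_features <- function(levels, n_levels) {
  M <- cpp_ngtdm(levels, dim(levels), n_levels)
  n_i <- M[, 1]
  s_i <- M[, 2]
  N <- sum(n_i)
  p_i <- n_i / N
  act <- which(p_i > 0)
  ngp <- length(act)
  iv <- seq_len(n_levels)
  denom_c <- sum(p_i * s_i)
  coarse <- if (denom_c > 0) 1 / denom_c else 1e6
  contrast <- if (ngp > 1) {
    sum(outer(p_i[act], p_i[act]) *
        outer(iv[act], iv[act], `-`)^2) / (ngp * (ngp - 1)) * sum(s_i) / N
  } else 0
  busy_den <- sum(abs(outer(iv[act] * p_i[act], iv[act] * p_i[act], `-`)))
  busyness <- if (busy_den > 0) denom_c / busy_den else 0
  cmplx <- if (N > 0 && ngp > 1) {
    acc <- 0
    for (a in act) for (b in act)
      acc <- acc + abs(a - b) * (p_i[a] * s_i[a] + p_i[b] * s_i[b]) /
        (p_i[a] + p_i[b])
    acc / N
  } else 0
  strength <- if (sum(s_i) > 0 && ngp > 1) {
    sum(outer(p_i[act], p_i[act], `+`) *
        outer(iv[act], iv[act], `-`)^2) / sum(s_i)
  } else 0
  c(Coarseness = coarse, Contrast = contrast, Busyness = busyness,
    Complexity = cmplx, Strength = strength)
}
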