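# Internal utilities: seed scoping, deterministic hashing, stratified folds,
# separable smoothing.

# Evaluate expr under a temporary RNG state; the caller's stream is restored.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# 32-bit FNV-1a string hash, kept in double arithmetic (exact below 2^53).
fnv_hash <- function(x) {
  vapply(as.character(x), function(s) {
    h <- 2166136261
    for (b in utf8ToInt(s)) {
      h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
      h <- (h * 16777619) %% 2^31
    }
    h
  }, numeric(1), USE.NAMES = FALSE)
}

#' Deterministic stratified cross-validation folds
#'
#' Fold membership depends on the case identifier and the seed, not on row
#' order: within each class, cases are sorted by a hash of `paste(seed, id)`
#' and dealt to folds cyclically. Permuting the rows of a table therefore
#' leaves every case's fold unchanged.
#'
#' @param case_ids character or coercible vector of unique case identifiers.
#' @param y binary labels (factor, logical or 0/1).
#' @param k number of folds.
#' @param seed integer seed.
#' @return Integer vector of fold assignments in `1..k`, aligned with
#'   `case_ids`.
#' @export
stratified_folds <- function(case_ids, y, k = 10, seed = 1L) {
  case_ids <- as.character(case_ids)
  if (anyDuplicated(case_ids)) stop("case ids must be unique")
  k <- as.integer(k)
  if (k < 2) stop("need at least 2 folds")
  y <- as.integer(as.factor(y))
  fold <- integer(length(case_ids))
  offset <- 0L
  for (cls in sort(unique(y))) {
    i <- which(y == cls)
    h <- fnv_hash(paste0(seed, "#", case_ids[i]))
    ord <- i[order(h, case_ids[i])]
    fold[ord] <- (offset + seq_along(ord) - 1L) %% k + 1L
    offset <- offset + length(ord)
  }
  fold
}

#' Separable Gaussian smoothing of a 3D array
#'
#' Per-axis Gaussian convolution (sigma in voxels), truncated at 4 sigma
#' with per-position weight renormalization at the boundaries. Used by the
#' synthetic generator's random fields and by the shape-feature
#' anti-aliasing.
#'
#' @param a 3D numeric array.
#' @param sigma smoothing sigma in voxels (scalar or per-axis length 3).
#' @return Smoothed array of the same dimensions.
#' @export
smooth3d <- function(a, sigma) {
  if (length(sigma) == 1L) sigma <- rep(sigma, 3)
  for (ax in 1:3) {
    if (sigma[ax] <= 0) next
    r <- max(1L, ceiling(4 * sigma[ax]))
    k <- stats::dnorm(seq(-r, r), sd = sigma[ax])
    k <- k / sum(k)
    a <- conv_axis(a, k, ax)
  }
  a
}

# Convolve a 3D array along one axis with kernel k (odd length), using
# matrix multiplication on the unfolded array. Zero padding outside, with
# per-position weight renormalization.
conv_axis <- function(a, k, ax, renormalize = TRUE) {
  d <- dim(a)
  n <- d[ax]
  r <- (length(k) - 1L) / 2L
  # band matrix W: n x n, W[i, j] = k[j - i + r + 1]
  W <- matrix(0, n, n)
  for (off in -r:r) {
    i <- seq_len(n)
    j <- i + off
    ok <- j >= 1 & j <= n
    W[cbind(i[ok], j[ok])] <- k[off + r + 1]
  }
  if (renormalize) W <- W / rowSums(W)
  perm <- c(ax, setdiff(1:3, ax))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = n)
  res <- W %*% m
  out <- array(res, dim = d[perm])
  aperm(out, order(perm))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
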