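test_that("first-order statistics match direct computation", {
  expect_equal(first_order_features(c(1, 2, 3, 4))[["Mean"]], 2.5)
  cst <- first_order_features(rep(5, 12))
  expect_equal(cst[["Variance"]], 0)
  expect_equal(cst[["Entropy"]], 0)
  expect_equal(cst[["Uniformity"]], 1)
  set.seed(10)
  x <- rnorm(100, sd = 120)
  lv <- discretize_gray_levels(x, 25)
  fo <- first_order_features(x, levels = lv)
  p <- as.numeric(table(lv)) / length(x)
  expect_equal(fo[["Entropy"]], -sum(p * log2(p)))
  expect_equal(fo[["Energy"]], sum(x^2))
  expect_equal(fo[["RootMeanSquared"]], sqrt(mean(x^2)))
  expect_error(first_order_features(numeric(0)), "empty")
})

test_that("shape features behave on canonical masks", {
  m1 <- array(FALSE, c(5, 5, 5))
  m1[3, 3, 3] <- TRUE
  s1 <- shape_features(m1, c(1, 1, 1))
  expect_equal(s1[["VoxelVolume"]], 1)
  m2 <- array(FALSE, c(6, 5, 5))
  m2[3:4, 3, 3] <- TRUE
  expect_equal(shape_features(m2, c(1, 1, 1))[["Maximum3DDiameter"]], 1)
  # digital ball radius 8: sphericity approaches the analytic sphere limit
  d <- 25
  ctr <- 13
  ball <- array(FALSE, c(d, d, d))
  for (z in 1:d) for (y in 1:d)
    ball[, y, z] <- ((1:d) - ctr)^2 + (y - ctr)^2 + (z - ctr)^2 <= 64
  sph <- shape_features(ball, c(1, 1, 1))[["Sphericity"]]
  expect_gt(sph, 0.95)
  expect_lte(sph, 1.0)
  # intensity invariance: shape depends only on the mask
  expect_error(shape_features(array(FALSE, c(3, 3, 3)), c(1, 1, 1)), "empty")
})

test_that("every texture family matches its brute-force oracle", {
  set.seed(77)
  n_cases <- 100
  for (rep in seq_len(n_cases)) {
    dims <- sample(2:5, 3, replace = TRUE)
    ng <- sample(2:4, 1)
    lv <- random_levels(dims, ng)
    ng <- max(lv)
    # GLCM counts per direction
    got_glcm <- cpp_glcm(lv, dim(lv), ng, 1L)
    for (d in 1:13)
      expect_identical(matrix(got_glcm[, , d], ng, ng),
                       oracle_glcm_dir(lv, ng, oracle_dirs[d, ]),
                       info = sprintf("glcm rep %d dir %d", rep, d))
    # GLRLM counts per direction
    got_rlm <- cpp_glrlm(lv, dim(lv), ng)
    for (d in 1:13) {
      oracle <- oracle_glrlm_dir(lv, ng, oracle_dirs[d, ])
      got <- matrix(got_rlm[, , d], ng, dim(got_rlm)[2])
      expect_identical(got[, seq_len(ncol(oracle)), drop = FALSE],
                       oracle[, seq_len(ncol(oracle)), drop = FALSE],
                       info = sprintf("glrlm rep %d dir %d", rep, d))
      if (ncol(got) > ncol(oracle))
        expect_true(all(got[, (ncol(oracle) + 1):ncol(got)] == 0))
    }
    # GLSZM zones as multisets of (level, size)
    got_z <- cpp_glszm_zones(lv, dim(lv))
    oracle_z <- oracle_glszm_zones(lv)
    expect_identical(
      got_z[order(got_z[, 1], got_z[, 2]), , drop = FALSE],
      oracle_z[order(oracle_z[, 1], oracle_z[, 2]), , drop = FALSE],
      info = paste("glszm rep", rep))
    # GLDM dependence counts
    expect_identical(unname(cpp_gldm(lv, dim(lv), 0L))[seq_len(ng), ],
                     unname(oracle_gldm(lv, ng, 0))[seq_len(ng), ],
                     info = paste("gldm rep", rep))
    # NGTDM n_i and s_i
    got_n <- cpp_ngtdm(lv, dim(lv), ng)
    oracle_n <- oracle_ngtdm(lv, ng)
    expect_equal(unname(got_n), unname(oracle_n), tolerance = 1e-12,
                 info = paste("ngtdm rep", rep))
  }
})

test_that("texture matrix invariants hold", {
  set.seed(30)
  lv <- random_levels(c(5, 5, 4), 4)
  ng <- max(lv)
  n_roi <- sum(lv > 0)
  # GLRLM: run-length-weighted total equals ROI voxel count per direction
  rlm <- cpp_glrlm(lv, dim(lv), ng)
  for (d in 1:13) {
    R <- matrix(rlm[, , d], ng, dim(rlm)[2])
    expect_equal(sum(R %*% seq_len(ncol(R))), n_roi)
  }
  # GLSZM: zone-size-weighted total equals ROI voxel count
  z <- cpp_glszm_zones(lv, dim(lv))
  expect_equal(sum(z[, 2]), n_roi)
  # normalized GLCM sums to 1 per direction with pairs
  counts <- cpp_glcm(lv, dim(lv), ng, 1L)
  for (d in 1:13) {
    P <- counts[, , d] + t(counts[, , d])
    if (sum(P) > 0) expect_equal(sum(P / sum(P)), 1)
  }
})

test_that("degenerate ROIs follow the documented conventions", {
  one <- array(0L, c(1, 1, 1))
  one[1] <- 1L
  g <- glcm_features(one, 1L)
  expect_equal(g[["Contrast"]], 0)
  expect_equal(g[["Correlation"]], 1)
  expect_equal(g[["JointEnergy"]], 1)
  cst <- array(1L, c(3, 3, 3))
  expect_equal(glcm_features(cst, 1L)[["Contrast"]], 0)
  expect_equal(glcm_features(cst, 1L)[["JointEnergy"]], 1)
  # constant 3x3x3 ROI: one zone of size 27
  z <- cpp_glszm_zones(cst, dim(cst))
  expect_identical(dim(z), c(1L, 2L))
  expect_identical(z[1, 2], 27L)
  expect_equal(ngtdm_features(cst, 1L)[["Contrast"]], 0)
})

test_that("checkerboard maximizes GLCM contrast over equal-count images", {
  # exhaustive check over all 3x3 binary slices with levels {1, 2}
  base <- expand.grid(rep(list(1:2), 9))
  contrast_h <- function(v) {
    lv <- array(0L, c(3, 3, 1))
    lv[, , 1] <- matrix(as.integer(v), 3, 3)
    C <- oracle_glcm_dir(lv, 2, c(1, 0, 0))
    P <- C + t(C)
    sum(P / sum(P) * (row(P) - col(P))^2)
  }
  all_c <- apply(base, 1, contrast_h)
  checker <- c(1, 2, 1, 2, 1, 2, 1, 2, 1)
  expect_equal(contrast_h(checker), max(all_c))
})

test_that("texture features are invariant to global intensity shifts", {
  set.seed(11)
  v <- array(rnorm(8^3, 0, 100), c(8, 8, 8))
  m <- array(runif(8^3) < 0.8, c(8, 8, 8))
  img1 <- volume_image(v)
  img2 <- volume_image(v + 500)
  cfg <- feature_config(families = c("glcm", "glrlm", "glszm", "gldm",
                                     "ngtdm"))
  f1 <- extract_features(img1, m, cfg = cfg)
  f2 <- extract_features(img2, m, cfg = cfg)
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("filter bank behaves analytically", {
  z <- volume_image(array(0, c(8, 8, 8)))
  wb <- wavelet_subbands(z)
  expect_length(wb, 8)
  expect_true(all(vapply(wb, function(b) all(b$values == 0), logical(1))))
  # LoG of an impulse equals the sampled analytic LoG kernel
  n <- 21
  imp <- array(0, c(n, n, n))
  imp[11, 11, 11] <- 1
  sig <- 2
  out <- log_filter(volume_image(imp), sig)$values
  an <- array(0, c(n, n, n))
  for (z2 in 1:n) for (y in 1:n) for (x in 1:n) {
    r2 <- (x - 11)^2 + (y - 11)^2 + (z2 - 11)^2
    an[x, y, z2] <- (r2 / sig^4 - 3 / sig^2) *
      exp(-r2 / (2 * sig^2)) / ((2 * pi)^1.5 * sig^3)
  }
  expect_lt(max(abs(out - an)), 1e-4)
  expect_error(log_filter(z, -1), "> 0")
  # enabling filters multiplies the non-shape feature count
  base <- feature_count(feature_config())
  both <- feature_count(feature_config(filters = c("wavelet", "log"),
                                       log_sigmas = c(1, 2)))
  expect_identical(both, 10L + (1L + 10L) * (base - 10L))
})

test_that("extract_all covers the triplet consistently", {
  set.seed(12)
  spec <- tiny_spec()
  cs <- simulate_nodule(spec, "IAC", seed = 5)
  trip <- suppressWarnings(build_roi_triplet(cs$gtv_mask,
                                             cs$image$spacing, 5))
  f <- extract_all(cs$image, trip)
  expect_named(f, c("GTV", "GPTV", "GPR"))
  expect_gt(f$GPTV[["original_shape_VoxelVolume"]],
            f$GTV[["original_shape_VoxelVolume"]])
  expect_length(f$GTV, feature_count())
  f2 <- extract_all(cs$image, trip)
  expect_identical(f, f2)
})
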