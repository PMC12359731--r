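# Internal compiled kernels under test (not part of the exported API).
cpp_glcm <- periradiomics:::cpp_glcm
cpp_glrlm <- periradiomics:::cpp_glrlm
cpp_glszm_zones <- periradiomics:::cpp_glszm_zones
cpp_gldm <- periradiomics:::cpp_gldm
cpp_ngtdm <- periradiomics:::cpp_ngtdm

# Independent brute-force oracles for the texture families. These enumerate
# voxel pairs, runs, zones, dependencies and neighbourhoods directly with
# plain loops over array indices, sharing no code with the package kernels.

oracle_dirs <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1), c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

oracle_in_bounds <- function(p, d) all(p >= 1) && all(p <= d)

# co-occurrence counts for one direction by scanning every voxel pair
oracle_glcm_dir <- function(lv, ng, dir, distance = 1) {
  d <- dim(lv)
  C <- matrix(0, ng, ng)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lv[x, y, z]
    if (a == 0) next
    q <- c(x, y, z) + dir * distance
    if (!oracle_in_bounds(q, d)) next
    b <- lv[q[1], q[2], q[3]]
    if (b == 0) next
    C[a, b] <- C[a, b] + 1
  }
  C
}

# run-length counts for one direction by walking each maximal run
oracle_glrlm_dir <- function(lv, ng, dir) {
  d <- dim(lv)
  R <- matrix(0, ng, max(d))
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lv[x, y, z]
    if (a == 0) next
    prev <- c(x, y, z) - dir
    if (oracle_in_bounds(prev, d) && lv[prev[1], prev[2], prev[3]] == a)
      next # not a run start
    len <- 1
    q <- c(x, y, z) + dir
    while (oracle_in_bounds(q, d) && lv[q[1], q[2], q[3]] == a) {
      len <- len + 1
      q <- q + dir
    }
    R[a, len] <- R[a, len] + 1
  }
  R
}

oracle_neighbors26 <- function(p, d) {
  out <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    q <- p + c(dx, dy, dz)
    if (oracle_in_bounds(q, d)) out[[length(out) + 1]] <- q
  }
  out
}

# zones of equal level (26-connected) by repeated region growing
oracle_glszm_zones <- function(lv) {
  d <- dim(lv)
  seen <- array(FALSE, d)
  zones <- list()
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (lv[x, y, z] == 0 || seen[x, y, z]) next
    level <- lv[x, y, z]
    frontier <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(frontier)) {
      p <- frontier[[1]]
      frontier <- frontier[-1]
      size <- size + 1
      for (q in oracle_neighbors26(p, d)) {
        if (!seen[q[1], q[2], q[3]] && lv[q[1], q[2], q[3]] == level) {
          seen[q[1], q[2], q[3]] <- TRUE
          frontier[[length(frontier) + 1]] <- q
        }
      }
    }
    zones[[length(zones) + 1]] <- c(level, size)
  }
  matrix(as.integer(do.call(rbind, zones)), ncol = 2)
}

oracle_gldm <- function(lv, ng, alpha = 0) {
  d <- dim(lv)
  D <- matrix(0, ng, 27)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lv[x, y, z]
    if (a == 0) next
    dep <- 0
    for (q in oracle_neighbors26(c(x, y, z), d)) {
      b <- lv[q[1], q[2], q[3]]
      if (b != 0 && abs(b - a) <= alpha) dep <- dep + 1
    }
    D[a, dep + 1] <- D[a, dep + 1] + 1
  }
  D
}

oracle_ngtdm <- function(lv, ng) {
  d <- dim(lv)
  n_i <- numeric(ng)
  s_i <- numeric(ng)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lv[x, y, z]
    if (a == 0) next
    vals <- c()
    for (q in oracle_neighbors26(c(x, y, z), d)) {
      b <- lv[q[1], q[2], q[3]]
      if (b != 0) vals <- c(vals, b)
    }
    n_i[a] <- n_i[a] + 1
    if (length(vals)) s_i[a] <- s_i[a] + abs(a - mean(vals))
  }
  cbind(n_i, s_i)
}

# random levels array with a random ROI (guaranteed nonempty)
random_levels <- function(dims, ng, p_roi = 0.7) {
  lv <- array(0L, dims)
  roi <- array(stats::runif(prod(dims)) < p_roi, dims)
  if (!any(roi)) roi[sample(prod(dims), 1)] <- TRUE
  lv[roi] <- sample.int(ng, sum(roi), replace = TRUE)
  # renumber so levels are contiguous 1..max
  u <- sort(unique(lv[lv > 0]))
  lv2 <- array(0L, dims)
  for (i in seq_along(u)) lv2[lv == u[i]] <- i
  lv2
}

# AUC by explicit pair counting
oracle_auc <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# small deterministic test cohort spec (kept small for speed)
tiny_spec <- function(...) {
  cohort_spec(n_mia = 4, n_iac = 5, grid_mm = 24, seed = 99, ...)
}
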