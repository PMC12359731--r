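#' Reference cohort covariate counts
#'
#' Per-class covariate counts and continuous summaries for the subcentimeter
#' lung adenocarcinoma reference cohort (53 MIA, 89 IAC) that the synthetic
#' generator's defaults emulate: presence counts for twelve binary CT/
#' demographic covariates and median/IQR for age, BMI and maximum nodule
#' diameter.
#'
#' @return A data.frame with columns `variable`, `type`, `mia`, `iac`.
#' @export
reference_cohort_counts <- function() {
  path <- system.file("extdata", "reference_cohort_counts.csv",
                      package = "periradiomics", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

ref_value <- function(ref, variable, cls) ref[ref$variable == variable, cls]

#' Synthetic cohort specification
#'
#' Defines the study conditions for the synthetic 3D-nodule cohort: class
#' sizes, class-conditional diameter distributions (median/IQR on a (3, 10]
#' mm support, matching the subcentimeter definition), subsolid fractions,
#' binary covariate prevalences, and the two planted image effects —
#' `texture_effect`, the intratumoral high-frequency heterogeneity amplitude
#' added to IAC nodules (HU), and `peritumoral_effect`, the shell
#' densification / vessel-strand amplitude in the IAC peritumoral region
#' (HU). Defaults reproduce the reference cohort margins
#' ([reference_cohort_counts()]).
#'
#' Diameters are drawn from a Beta distribution rescaled to (`diameter_min`,
#' 10] mm whose parameters are solved numerically so that the class median
#' and IQR equal the requested values exactly.
#'
#' @param n_mia,n_iac class sizes (>= 1).
#' @param diameter_median_mm,diameter_iqr_mm length-2 vectors (MIA, IAC) in
#'   mm; medians must lie in (0, 10].
#' @param subsolid_fraction length-2 vector of subsolid probabilities.
#' @param covariate_prevalences named list; each element a length-2 vector
#'   `c(mia, iac)` of presence probabilities in \[0, 1\].
#' @param texture_effect,peritumoral_effect nonnegative amplitudes in HU.
#' @param voxel_spacing_mm length-3 voxel spacing of simulated volumes.
#' @param grid_mm physical edge length of the simulated cube (mm).
#' @param diameter_min_mm lower bound of the diameter support (mm).
#' @param seed master seed; per-case seeds are derived by the splitting rule
#'   `(seed * 1000003 + case_index) mod (2^31 - 1)`.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_mia = 53, n_iac = 89,
                        diameter_median_mm = c(8, 9),
                        diameter_iqr_mm = c(2.65, 2),
                        subsolid_fraction = NULL,
                        covariate_prevalences = NULL,
                        texture_effect = 60,
                        peritumoral_effect = 40,
                        voxel_spacing_mm = c(1, 1, 1),
                        grid_mm = 28,
                        diameter_min_mm = 3,
                        seed = 1L) {
  ref <- reference_cohort_counts()
  n_ref <- c(mia = ref_value(ref, "n", "mia"), iac = ref_value(ref, "n", "iac"))
  if (is.null(subsolid_fraction))
    subsolid_fraction <- c(1 - ref_value(ref, "solid_type", "mia") / n_ref[1],
                           1 - ref_value(ref, "solid_type", "iac") / n_ref[2])
  if (is.null(covariate_prevalences)) {
    bin <- ref[ref$type == "present_count", ]
    covariate_prevalences <- lapply(seq_len(nrow(bin)), function(i)
      c(bin$mia[i] / n_ref[1], bin$iac[i] / n_ref[2]))
    names(covariate_prevalences) <- bin$variable
  }
  stopifnot(n_mia >= 1, n_iac >= 1)
  if (any(diameter_median_mm <= 0) || any(diameter_median_mm > 10))
    stop("diameter medians must lie in (0, 10] mm (subcentimeter nodules)")
  if (texture_effect < 0 || peritumoral_effect < 0)
    stop("effect amplitudes must be nonnegative")
  for (nm in names(covariate_prevalences)) {
    p <- covariate_prevalences[[nm]]
    if (any(p < 0) || any(p > 1)) stop("prevalence outside [0,1]: ", nm)
  }
  if (any(subsolid_fraction < 0) || any(subsolid_fraction > 1))
    stop("subsolid_fraction outside [0,1]")
  beta_par <- lapply(1:2, function(k)
    solve_beta_diameter(diameter_median_mm[k], diameter_iqr_mm[k],
                        lo = diameter_min_mm, hi = 10))
  structure(list(
    n_mia = as.integer(n_mia), n_iac = as.integer(n_iac),
    diameter_median_mm = diameter_median_mm,
    diameter_iqr_mm = diameter_iqr_mm,
    diameter_min_mm = diameter_min_mm,
    beta_par = beta_par,
    subsolid_fraction = as.numeric(subsolid_fraction),
    covariate_prevalences = covariate_prevalences,
    texture_effect = texture_effect,
    peritumoral_effect = peritumoral_effect,
    voxel_spacing_mm = as.numeric(voxel_spacing_mm),
    grid_mm = grid_mm,
    seed = as.integer(seed)), class = "cohort_spec")
}

# Solve Beta(a, b) on [lo, hi] for a given median and IQR.
solve_beta_diameter <- function(med, iqr, lo = 3, hi = 10) {
  m <- (med - lo) / (hi - lo)
  q <- iqr / (hi - lo)
  if (m <= 0 || m >= 1) stop("median outside diameter support")
  obj <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    (stats::qbeta(0.5, a, b) - m)^2 +
      (stats::qbeta(0.75, a, b) - stats::qbeta(0.25, a, b) - q)^2
  }
  fit <- stats::optim(c(log(4), log(4)), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  list(a = exp(fit$par[1]), b = exp(fit$par[2]), lo = lo, hi = hi)
}

draw_diameter <- function(beta_par, n = 1) {
  with(beta_par, lo + (hi - lo) * stats::qbeta(stats::runif(n), a, b))
}

case_seed <- function(spec, index) {
  as.integer((as.numeric(spec$seed) * 1000003 + index) %% 2147483647)
}

#' Simulate one synthetic subcentimeter nodule
#'
#' Renders a nodule as a randomly rotated superellipsoid with a smooth
#' random boundary perturbation in a lung-like background (HU about
#' Normal(-850, 50), clipped to \[-1024, -500\]). Subsolid cores draw from
#' Normal(-450, 60) HU, solid cores from Normal(-30, 40) HU. IAC nodules
#' additionally receive spatially structured intratumoral noise of amplitude
#' `texture_effect` and a peritumoral shell densification of amplitude
#' `peritumoral_effect`; bright vessel-like strands (radius 0.5 mm, -100 HU)
#' cross the shell with a probability that increases with
#' `peritumoral_effect` for IAC cases.
#'
#' The returned `max_diameter_mm` covariate is mask-derived: the maximum
#' caliper distance between surface voxel centres plus the mean voxel
#' extent. Draws whose rendered diameter exceeds 10 mm are redrawn (error
#' after 8 attempts).
#'
#' @param spec a [cohort_spec].
#' @param label `"MIA"` or `"IAC"`.
#' @param seed integer seed; the case is fully determined by
#'   `(spec, label, seed)`.
#' @return A list of class `synthetic_case`: `image` ([volume_image]),
#'   `gtv_mask` (logical array), `label`, `covariates` (one-row data.frame
#'   with `max_diameter_mm` and `subsolid`), `seed_used`.
#' @export
simulate_nodule <- function(spec, label = c("MIA", "IAC"), seed = 1L) {
  label <- match.arg(label)
  k <- if (label == "MIA") 1L else 2L
  sp <- spec$voxel_spacing_mm
  dims <- pmax(8L, as.integer(round(spec$grid_mm / sp)))
  with_seed(seed, {
    for (attempt in 1:8) {
      d <- draw_diameter(spec$beta_par[[k]])
      mask <- render_superellipsoid(dims, sp, d)
      if (is.null(mask)) next
      dm <- attr(mask, "diameter_mm")
      if (dm <= 10) break
      mask <- NULL
    }
    if (is.null(mask))
      stop("could not render a subcentimeter nodule after 8 attempts")
    attr(mask, "diameter_mm") <- NULL
    nvox <- prod(dims)
    v <- array(pmin(pmax(stats::rnorm(nvox, -850, 50), -1024), -500), dims)
    # class-independent per-case variability: parenchymal texture of random
    # amplitude and a global HU calibration offset (scanner / inspiration
    # depth); these mask small mean shifts, as peritumoral noise does in
    # real cohorts
    par_amp <- 20 * stats::runif(1, 0.5, 1.5)
    pf <- smooth3d(array(stats::rnorm(nvox), dims), 1.2)
    v <- v + par_amp * pf / stats::sd(pf)
    hu_offset <- stats::rnorm(1, 0, 15)
    subsolid <- stats::runif(1) < spec$subsolid_fraction[k]
    core <- if (subsolid) c(-450, 60) else c(-30, 40)
    nin <- sum(mask)
    v[mask] <- stats::rnorm(nin, core[1], core[2])
    # One latent invasion severity per case (exponential, mean 1) scales
    # both planted effects: cross-tumor variability keeps single features
    # off the AUC ceiling, and the peritumoral change is a lower-SNR proxy
    # of the same severity the core expresses directly. The intratumoral
    # effect combines densification (mean shift) with high-frequency
    # heterogeneity; the peritumoral effect is confined to a thin 2.5 mm
    # inner rim (microscopic invasion extent), so it is diluted over the
    # full 5 mm shell.
    severity <- stats::rexp(1)
    if (label == "IAC" && spec$texture_effect > 0) {
      amp <- spec$texture_effect * severity
      tx <- smooth3d(array(stats::rnorm(nvox), dims), 0.7)
      tx <- tx / stats::sd(tx)
      v[mask] <- v[mask] + amp * (0.2 + tx[mask])
    }
    if (label == "IAC" && spec$peritumoral_effect > 0) {
      rim <- dilate_mask(mask, sp, 2.5) & !mask
      if (any(rim)) {
        amp <- spec$peritumoral_effect * severity
        g <- smooth3d(array(stats::rnorm(nvox), dims), 1.5)
        g <- g / stats::sd(g)
        v[rim] <- v[rim] + amp * (0.5 + 0.5 * tanh(g[rim]))
      }
    }
    p_strand <- min(0.95, 0.4 +
                      if (label == "IAC") spec$peritumoral_effect / 150 else 0)
    n_strand <- stats::rbinom(1, 3, p_strand)
    if (n_strand > 0) v <- add_strands(v, mask, sp, n_strand)
    v <- pmin(pmax(v + hu_offset, -1024), 400)
    cov <- data.frame(max_diameter_mm = dm, subsolid = subsolid)
    structure(list(image = volume_image(v, spacing = sp),
                   gtv_mask = mask, label = label,
                   covariates = cov, seed_used = as.integer(seed)),
              class = "synthetic_case")
  })
}

# Superellipsoid (exponent 2.5) with smooth boundary perturbation. The
# radial scale is calibrated in two correction steps so that the measured
# caliper diameter (surface-voxel centres plus voxel extent) matches the
# drawn diameter. Returns the largest 6-connected component with the
# measured diameter as attribute "diameter_mm", or NULL if degenerate.
render_superellipsoid <- function(dims, sp, d) {
  ctr <- (dims + 1) / 2 + stats::runif(3, -0.5, 0.5)
  ratio <- c(1, stats::runif(1, 0.8, 1), stats::runif(1, 0.8, 1))
  ax <- d / 2 * ratio
  R <- rand_rotation()
  g1 <- (seq_len(dims[1]) - ctr[1]) * sp[1]
  g2 <- (seq_len(dims[2]) - ctr[2]) * sp[2]
  g3 <- (seq_len(dims[3]) - ctr[3]) * sp[3]
  X <- array(g1, dims)
  Y <- array(rep(g2, each = dims[1]), dims)
  Z <- array(rep(g3, each = dims[1] * dims[2]), dims)
  U1 <- R[1, 1] * X + R[1, 2] * Y + R[1, 3] * Z
  U2 <- R[2, 1] * X + R[2, 2] * Y + R[2, 3] * Z
  U3 <- R[3, 1] * X + R[3, 2] * Y + R[3, 3] * Z
  e <- 2.5
  rho <- (abs(U1 / ax[1])^e + abs(U2 / ax[2])^e + abs(U3 / ax[3])^e)^(1 / e)
  G <- smooth3d(array(stats::rnorm(prod(dims)), dims), 2)
  G <- G / stats::sd(G)
  thr <- 1 + 0.06 * G
  s <- 1
  mask <- NULL
  dm <- NA_real_
  for (iter in 1:3) {
    m <- rho <= s * thr
    if (!any(m)) return(NULL)
    m <- largest_component(array(m, dims))
    dm <- mask_max_diameter(m, sp, include_extent = TRUE)
    mask <- m
    if (abs(dm - d) < 0.25) break
    s <- s * d / dm
  }
  attr(mask, "diameter_mm") <- dm
  mask
}

rand_rotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qrd)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Bright strands: line segments of radius ~0.5 mm at -100 HU crossing the
# nodule boundary outward.
add_strands <- function(v, mask, sp, n_strand) {
  dims <- dim(v)
  surf_idx <- which(mask_surface(mask), arr.ind = TRUE)
  ctr <- colMeans(which(mask, arr.ind = TRUE))
  for (s in seq_len(n_strand)) {
    p0 <- surf_idx[sample.int(nrow(surf_idx), 1), ]
    dir <- (p0 - ctr) * sp + stats::rnorm(3, 0, 0.5)
    dir <- dir / sqrt(sum(dir^2))
    steps <- seq(0, 6, by = 0.3)
    for (t in steps) {
      pos <- p0 + t * dir / sp
      ip <- round(pos)
      if (any(ip < 1) || any(ip > dims)) break
      if (!mask[ip[1], ip[2], ip[3]])
        v[ip[1], ip[2], ip[3]] <- max(v[ip[1], ip[2], ip[3]], -100)
    }
  }
  v
}

#' Simulate a clinical covariate table
#'
#' Draws the binary covariates with their class-conditional prevalences and
#' the continuous covariates (age, BMI, max diameter) from the
#' specification. In `exact_counts` mode each binary covariate has exactly
#' `round(prevalence * n)` positives per class (randomly placed), which
#' reproduces the integer counts implied by the reference cohort
#' percentages.
#'
#' @param spec a [cohort_spec].
#' @param seed integer seed.
#' @param exact_counts logical; draw counts exactly rather than binomially.
#' @return A data.frame with `case_id`, `label` (factor MIA/IAC), `age`,
#'   `bmi`, `max_diameter_mm`, and one 0/1 column per binary covariate.
#' @export
simulate_clinical_table <- function(spec, seed = spec$seed,
                                    exact_counts = FALSE) {
  ref <- reference_cohort_counts()
  n <- c(spec$n_mia, spec$n_iac)
  with_seed(seed, {
    rows <- lapply(1:2, function(k) {
      cls <- c("MIA", "IAC")[k]
      nk <- n[k]
      df <- data.frame(
        case_id = sprintf("%s%03d", tolower(cls), seq_len(nk)),
        label = cls,
        age = stats::rnorm(nk, ref_value(ref, "age_median", c("mia", "iac")[k]),
                           ref_value(ref, "age_iqr", c("mia", "iac")[k]) / 1.349),
        bmi = stats::rnorm(nk, ref_value(ref, "bmi_median", c("mia", "iac")[k]),
                           ref_value(ref, "bmi_iqr", c("mia", "iac")[k]) / 1.349),
        max_diameter_mm = draw_diameter(spec$beta_par[[k]], nk))
      for (nm in names(spec$covariate_prevalences)) {
        p <- spec$covariate_prevalences[[nm]][k]
        df[[nm]] <- if (exact_counts) {
          ones <- round(p * nk)
          sample(rep(c(1L, 0L), c(ones, nk - ones)))
        } else stats::rbinom(nk, 1, p)
      }
      df
    })
    out <- rbind(rows[[1]], rows[[2]])
    out$label <- factor(out$label, levels = c("MIA", "IAC"))
    out
  })
}

#' Simulate a full imaging cohort
#'
#' Generates the clinical table and one synthetic nodule per case; the
#' mask-derived `max_diameter_mm` replaces the tabular draw so image and
#' table agree. Per-case seeds derive deterministically from the master
#' seed, so the whole cohort is reproducible from the specification alone.
#'
#' @param spec a [cohort_spec].
#' @param exact_counts passed to [simulate_clinical_table()].
#' @return A list of class `synthetic_cohort`: `cases` (list of
#'   `synthetic_case`) and `clinical` (data.frame aligned with `cases`).
#' @export
simulate_cohort <- function(spec, exact_counts = FALSE) {
  clinical <- simulate_clinical_table(spec, seed = spec$seed,
                                      exact_counts = exact_counts)
  labels <- as.character(clinical$label)
  cases <- vector("list", nrow(clinical))
  for (i in seq_len(nrow(clinical))) {
    cs <- simulate_nodule(spec, labels[i], seed = case_seed(spec, i))
    clinical$max_diameter_mm[i] <- cs$covariates$max_diameter_mm
    cs$covariates <- cbind(clinical[i, setdiff(names(clinical), "label"),
                                    drop = FALSE],
                           row.names = NULL)
    cases[[i]] <- cs
  }
  structure(list(cases = cases, clinical = clinical, spec = spec),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Saves each case as a NIfTI image/mask pair, the covariates as CSV, and a
#' JSON manifest listing case ids, labels and seeds.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- cohort$clinical$case_id
  for (i in seq_along(cohort$cases)) {
    cs <- cohort$cases[[i]]
    write_volume(cs$image, file.path(dir, paste0(ids[i], "_image.nii.gz")))
    write_mask(volume_image(cs$gtv_mask * 1, cs$image$spacing,
                            cs$image$origin),
               file.path(dir, paste0(ids[i], "_mask.nii.gz")))
  }
  utils::write.csv(cohort$clinical, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  manifest <- list(cases = data.frame(
    case_id = ids, label = as.character(cohort$clinical$label),
    seed = vapply(cohort$cases, function(cs) cs$seed_used, integer(1)),
    image = paste0(ids, "_image.nii.gz"),
    mask = paste0(ids, "_mask.nii.gz")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
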