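#' ROC curve and AUC
#'
#' The empirical ROC over all observed score thresholds (classification rule
#' `score >= threshold` is positive). The AUC is computed as the
#' Mann-Whitney U statistic divided by `n1 * n0`, counting ties as 1/2,
#' which equals the trapezoidal area under the empirical curve.
#'
#' @param scores numeric vector.
#' @param labels binary labels; the second factor level (or 1) is positive.
#' @return An object of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `youden_cutoff`, plus the score/label data.
#' @export
roc_auc <- function(scores, labels) {
  y <- as.integer(as.factor(labels)) - 1L
  if (length(unique(y)) != 2) stop("both classes must be present")
  if (length(scores) != length(y)) stop("length mismatch")
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores))
  sens <- vapply(thr, function(t) mean(scores[y == 1] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[y == 0] < t), numeric(1))
  j <- sens + spec - 1
  cut <- thr[which(j == max(j))[1]] # ties -> lowest threshold
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, youden_cutoff = cut, scores = scores, y = y),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  i <- which(x$thresholds == x$youden_cutoff)
  cat(sprintf(
    "<roc_result> AUC %.3f; Youden cutoff %.3g (sens %.3f, spec %.3f)\n",
    x$auc, x$youden_cutoff, x$sensitivity[i], x$specificity[i]))
  invisible(x)
}

#' Youden-optimal threshold
#'
#' The observed threshold maximizing sensitivity + specificity - 1; ties
#' resolve to the lowest threshold.
#'
#' @param roc a `roc_result` from [roc_auc()].
#' @return The cutoff (scalar).
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  roc$youden_cutoff
}

# DeLong structural components: V10 (per positive) and V01 (per negative).
delong_components <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10 <- vapply(pos, function(a) mean(psi(a, neg)), numeric(1))
  v01 <- vapply(neg, function(b) mean(psi(pos, b)), numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong variance of an AUC and paired AUC comparison
#'
#' `delong_var()` returns the structural-components variance estimate of a
#' single AUC. `delong_test()` compares two paired score vectors evaluated
#' on the same cases, returning the difference z statistic and two-sided
#' normal p value.
#'
#' @param scores,scores_a,scores_b numeric score vectors on identical cases.
#' @param labels binary labels.
#' @return `delong_var`: the variance (scalar). `delong_test`: a list with
#'   `auc_a`, `auc_b`, `z`, `p`, `var_diff`.
#' @export
delong_var <- function(scores, labels) {
  y <- as.integer(as.factor(labels)) - 1L
  if (length(unique(y)) != 2) stop("both classes must be present")
  cmp <- delong_components(scores, y)
  stats::var(cmp$v10) / length(cmp$v10) + stats::var(cmp$v01) / length(cmp$v01)
}

#' @rdname delong_var
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  y <- as.integer(as.factor(labels)) - 1L
  if (length(unique(y)) != 2) stop("both classes must be present")
  if (length(scores_a) != length(y) || length(scores_b) != length(y))
    stop("scores must be paired on identical cases")
  ca <- delong_components(scores_a, y)
  cb <- delong_components(scores_b, y)
  n1 <- length(ca$v10)
  n0 <- length(ca$v01)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  d <- ca$auc - cb$auc
  if (var_diff <= 0) {
    if (d == 0) return(list(auc_a = ca$auc, auc_b = cb$auc, z = 0, p = 1,
                            var_diff = var_diff))
    stop("degenerate DeLong variance (zero) with unequal AUCs")
  }
  z <- d / sqrt(var_diff)
  list(auc_a = ca$auc, auc_b = cb$auc, z = z,
       p = 2 * stats::pnorm(-abs(z)), var_diff = var_diff)
}

#' AUC confidence intervals
#'
#' `delong_auc_ci()` is the normal-approximation interval using the DeLong
#' variance, truncated to \[0, 1\]. `bootstrap_auc_ci()` is the percentile
#' interval over stratified case resampling (default 2000 replicates).
#'
#' @inheritParams delong_var
#' @param level confidence level (default 0.95).
#' @param reps bootstrap replicates (>= 100).
#' @param seed integer seed.
#' @return Length-2 numeric vector `c(lower, upper)` with attribute
#'   `method`.
#' @export
delong_auc_ci <- function(scores, labels, level = 0.95) {
  auc <- roc_auc(scores, labels)$auc
  se <- sqrt(delong_var(scores, labels))
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- c(max(0, auc - z * se), min(1, auc + z * se))
  attr(ci, "method") <- "delong"
  ci
}

#' @rdname delong_auc_ci
#' @export
bootstrap_auc_ci <- function(scores, labels, reps = 2000, seed = 1L,
                             level = 0.95) {
  if (reps < 100) stop("use at least 100 bootstrap replicates")
  y <- as.integer(as.factor(labels)) - 1L
  if (length(unique(y)) != 2) stop("both classes must be present")
  i1 <- which(y == 1)
  i0 <- which(y == 0)
  aucs <- with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      idx <- c(sample(i1, replace = TRUE), sample(i0, replace = TRUE))
      roc_auc(scores[idx], y[idx])$auc
    }, numeric(1))
  })
  ci <- unname(stats::quantile(aucs, c((1 - level) / 2, 1 - (1 - level) / 2)))
  attr(ci, "method") <- "bootstrap_percentile"
  ci
}

#' Hosmer-Lemeshow calibration test
#'
#' Cases are grouped into `g` equal-count risk bins (deciles of risk by
#' default) with tied probabilities kept in one bin; bins left empty by ties
#' are merged with a warning. The statistic is
#' `sum((O - E)^2 / (E (1 - E / n_bin)))` with `g - 2` degrees of freedom.
#'
#' @param probabilities predicted event probabilities in \[0, 1\].
#' @param labels binary outcomes.
#' @param g number of bins (>= 3, default 10).
#' @return A list of class `calibration_result`: per-bin table (`n`,
#'   `observed`, `expected`, mean predicted), `statistic`, `df`, `p`.
#' @export
hosmer_lemeshow <- function(probabilities, labels, g = 10) {
  if (g < 3) stop("need at least 3 bins")
  y <- as.integer(as.factor(labels)) - 1L
  p <- as.numeric(probabilities)
  if (length(p) != length(y)) stop("length mismatch")
  br <- unique(stats::quantile(p, probs = seq(0, 1, length.out = g + 1)))
  if (length(br) - 1 < g)
    warning("ties collapsed ", g - (length(br) - 1), " bin(s)")
  bin <- cut(p, breaks = br, include.lowest = TRUE)
  nb <- tabulate(bin, nbins = nlevels(bin))
  keep <- nb > 0
  O <- tapply(y, bin, sum)[keep]
  E <- tapply(p, bin, sum)[keep]
  n_bin <- nb[keep]
  stat <- sum((O - E)^2 / (E * (1 - E / n_bin)))
  df <- sum(keep) - 2
  structure(list(
    bins = data.frame(n = n_bin, observed = as.numeric(O),
                      expected = as.numeric(E),
                      mean_predicted = as.numeric(E / n_bin)),
    statistic = stat, df = df,
    p = stats::pchisq(stat, df, lower.tail = FALSE)),
    class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> HL chi2 %.3f on %d df, p = %.4f (%d bins)\n",
              x$statistic, x$df, x$p, nrow(x$bins)))
  invisible(x)
}

#' Decision-curve analysis
#'
#' Net benefit of treating according to `probability >= p_t` at each
#' threshold probability `p_t`:
#' `NB(p_t) = TP/n - (FP/n) * p_t / (1 - p_t)`, together with the treat-all
#' reference `pi - (1 - pi) * p_t / (1 - p_t)` (`pi` = prevalence) and the
#' treat-none reference (identically 0). The reported `useful_range` is the
#' `p_t` interval on the grid where the model's net benefit exceeds both
#' references.
#'
#' @param probabilities predicted probabilities.
#' @param labels binary outcomes.
#' @param p_t threshold probability grid in (0, 1); values outside are
#'   dropped.
#' @return A list of class `decision_curve`: `p_t`, `net_benefit`,
#'   `treat_all`, `treat_none`, `prevalence`, `useful_range`.
#' @export
decision_curve <- function(probabilities, labels,
                           p_t = seq(0.01, 0.99, by = 0.01)) {
  y <- as.integer(as.factor(labels)) - 1L
  p <- as.numeric(probabilities)
  p_t <- p_t[p_t > 0 & p_t < 1]
  if (!length(p_t)) stop("empty threshold grid")
  n <- length(y)
  prev <- mean(y)
  w <- p_t / (1 - p_t)
  nb <- vapply(seq_along(p_t), function(i) {
    pos <- p >= p_t[i]
    sum(pos & y == 1) / n - sum(pos & y == 0) / n * w[i]
  }, numeric(1))
  ta <- prev - (1 - prev) * w
  useful <- p_t[nb > pmax(ta, 0)]
  structure(list(p_t = p_t, net_benefit = nb, treat_all = ta,
                 treat_none = rep(0, length(p_t)), prevalence = prev,
                 useful_range = if (length(useful))
                   range(useful) else c(NA_real_, NA_real_)),
            class = "decision_curve")
}

#' Pairwise DeLong comparison table
#'
#' All pairwise AUC comparisons among a named set of score vectors on
#' common cases (largest AUC first, mirroring the usual model-comparison
#' table layout).
#'
#' @param score_list named list of numeric score vectors, equal lengths.
#' @param labels binary labels for the common cases.
#' @return data.frame with `model_a`, `model_b`, `auc_a`, `auc_b`, `z`, `p`.
#' @export
compare_models <- function(score_list, labels) {
  if (is.null(names(score_list)) || any(names(score_list) == ""))
    stop("score_list must be fully named")
  n <- unique(vapply(score_list, length, integer(1)))
  if (length(n) != 1 || n != length(labels))
    stop("mismatched case sets across models")
  aucs <- vapply(score_list, function(s) roc_auc(s, labels)$auc, numeric(1))
  ord <- names(sort(aucs, decreasing = TRUE))
  rows <- list()
  for (i in seq_along(ord)) for (j in seq_along(ord)) {
    if (j <= i) next
    dt <- delong_test(score_list[[ord[i]]], score_list[[ord[j]]], labels)
    rows[[length(rows) + 1]] <- data.frame(
      model_a = ord[i], model_b = ord[j],
      auc_a = dt$auc_a, auc_b = dt$auc_b, z = dt$z, p = dt$p)
  }
  do.call(rbind, rows)
}
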