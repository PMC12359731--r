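#' Pearson chi-squared test for a contingency table
#'
#' Without correction the statistic on a 2x2 table equals
#' `n (ad - bc)^2 / (r1 r2 c1 c2)`; with the Yates continuity correction the
#' absolute difference is reduced by `n/2` first. General r x c tables use
#' the usual `sum((O - E)^2 / E)`.
#'
#' @param table integer matrix of nonnegative counts.
#' @param correction `"none"` (default) or `"yates"` (2x2 only).
#' @return A list of class `test_result`: `statistic`, `df`, `p`, `method`.
#' @export
pearson_chi2 <- function(table, correction = c("none", "yates")) {
  correction <- match.arg(correction)
  table <- as.matrix(table)
  if (any(table < 0) || sum(table) == 0) stop("invalid contingency table")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal total")
  if (correction == "yates" && !all(dim(table) == 2))
    stop("Yates correction applies to 2x2 tables")
  ht <- suppressWarnings(
    stats::chisq.test(table, correct = correction == "yates"))
  test_result(unname(ht$statistic), unname(ht$parameter), ht$p.value,
              if (correction == "yates") "yates" else "pearson")
}

test_result <- function(statistic, df, p, method) {
  structure(list(statistic = statistic, df = df, p = p, method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result %s> statistic %.4g%s, p = %.4g\n", x$method,
              x$statistic,
              if (!is.null(x$df) && !is.na(x$df))
                sprintf(" (df %s)", format(x$df)) else "", x$p))
  invisible(x)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p value: the sum of hypergeometric probabilities of all tables
#' with the observed margins that are no more probable than the observed
#' one.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return A `test_result` (statistic is the odds-ratio estimate).
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2)) stop("need a 2x2 table")
  ht <- stats::fisher.test(table)
  test_result(unname(ht$estimate), NA_integer_, ht$p.value, "fisher")
}

#' Wald odds ratio for a 2x2 table
#'
#' `OR = ad / bc` with confidence interval
#' `exp(log(OR) +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. If any cell is zero
#' the Haldane-Anscombe 0.5 correction is applied to every cell and the
#' result is flagged.
#'
#' @param table 2x2 matrix: rows = exposure (absent, present), columns =
#'   outcome (negative, positive).
#' @return A list of class `or_result`: `or`, `ci` (length 2), `p` (Wald),
#'   `corrected`.
#' @export
odds_ratio_wald <- function(table) {
  tb <- as.matrix(table)
  if (!all(dim(tb) == 2)) stop("need a 2x2 table")
  corrected <- any(tb == 0)
  if (corrected) tb <- tb + 0.5
  or <- (tb[2, 2] * tb[1, 1]) / (tb[1, 2] * tb[2, 1])
  se <- sqrt(sum(1 / tb))
  ci <- or * exp(c(-1.96, 1.96) * se)
  z <- log(or) / se
  structure(list(or = or, ci = ci, p = 2 * stats::pnorm(-abs(z)),
                 corrected = corrected), class = "or_result")
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("<or_result> OR %.3f (%.3f, %.3f), p = %.4g%s\n", x$or,
              x$ci[1], x$ci[2], x$p,
              if (x$corrected) " [Haldane corrected]" else ""))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Reports the U statistic of the first sample, the tie-corrected normal
#' z with continuity correction, and the p value. For `n1 + n2 <= 12` the
#' p value comes from exact enumeration of all group assignments of the
#' pooled values (ties included); otherwise from the normal approximation.
#'
#' @param x,y numeric samples (both nonempty).
#' @return A `test_result` with fields `statistic` (U), `z`, `p`.
#' @export
mann_whitney_u <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  if (!n1 || !n2) stop("both samples must be nonempty")
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(pooled)
  n <- n1 + n2
  sig2 <- n1 * n2 / 12 * (n + 1 - sum(ties^3 - ties) / (n * (n - 1)))
  z <- if (sig2 > 0) (U - mu - sign(U - mu) * 0.5) / sqrt(sig2) else 0
  if (n <= 12) {
    obs_dev <- abs(U - mu)
    combs <- utils::combn(n, n1)
    us <- apply(combs, 2, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
    p <- mean(abs(us - mu) >= obs_dev - 1e-9)
    method <- "mwu_exact"
  } else {
    p <- if (sig2 > 0) 2 * stats::pnorm(-abs(z)) else 1
    method <- "mwu_normal"
  }
  out <- test_result(U, NA_integer_, p, method)
  out$z <- z
  out
}

#' Two-group comparison with a normality gate
#'
#' Shapiro-Wilk is applied to each group at alpha = 0.05; if both groups
#' look normal a pooled-variance t test is used, otherwise the Mann-Whitney
#' U test. Groups smaller than 3 skip the gate and default to the U test
#' with a warning. The dispatched method is recorded in the result.
#'
#' @param values numeric vector.
#' @param groups binary grouping vector.
#' @return A `test_result` with method `"ttest"`, `"mwu_exact"` or
#'   `"mwu_normal"`.
#' @export
group_compare <- function(values, groups) {
  g <- as.factor(groups)
  if (nlevels(g) != 2) stop("need exactly two groups")
  a <- values[g == levels(g)[1]]
  b <- values[g == levels(g)[2]]
  if (min(length(a), length(b)) < 3) {
    warning("groups too small for the normality gate; using Mann-Whitney U")
    return(mann_whitney_u(a, b))
  }
  normal <- function(v) {
    if (stats::sd(v) == 0) return(FALSE)
    stats::shapiro.test(v)$p.value >= 0.05
  }
  if (normal(a) && normal(b)) {
    ht <- stats::t.test(a, b, var.equal = TRUE)
    test_result(unname(ht$statistic), unname(ht$parameter), ht$p.value,
                "ttest")
  } else {
    mann_whitney_u(a, b)
  }
}

#' Univariable and multivariable logistic regression odds ratios
#'
#' Maximum-likelihood logistic regression (IRLS). In `"univariate"` mode
#' each predictor is fit alone; in `"multivariable"` mode all predictors
#' enter jointly. Wald 95% confidence intervals use z = 1.96. Separation is
#' flagged per model; rank-deficient designs raise an error naming the
#' collinear columns.
#'
#' @param data data.frame with binary `label` and the predictors.
#' @param predictors character vector of predictor column names.
#' @param type `"univariate"` or `"multivariable"`.
#' @return data.frame with `predictor`, `coef`, `or`, `ci_low`, `ci_high`,
#'   `p`, `separation`.
#' @export
logistic_regression <- function(data, predictors,
                                type = c("univariate", "multivariable")) {
  type <- match.arg(type)
  y <- as.factor(data$label)
  if (nlevels(y) != 2) stop("label must be binary")
  df <- data
  df$label_bin <- as.integer(y) - 1L
  fit_one <- function(preds) {
    X <- stats::model.matrix(stats::reformulate(preds), data = df)
    if (qr(X)$rank < ncol(X)) {
      stop("rank-deficient design; collinear columns among: ",
           paste(preds, collapse = ", "))
    }
    fit <- suppressWarnings(
      stats::glm(stats::reformulate(preds, response = "label_bin"),
                 family = stats::binomial(), data = df,
                 control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
    sm <- summary(fit)$coefficients
    sep <- !fit$converged || any(abs(stats::coef(fit)[-1]) > 20)
    rows <- rownames(sm)[-1]
    data.frame(predictor = rows, coef = sm[-1, 1], or = exp(sm[-1, 1]),
               ci_low = exp(sm[-1, 1] - 1.96 * sm[-1, 2]),
               ci_high = exp(sm[-1, 1] + 1.96 * sm[-1, 2]),
               p = sm[-1, 4], separation = sep, row.names = NULL)
  }
  if (type == "univariate") {
    do.call(rbind, lapply(predictors, fit_one))
  } else {
    fit_one(predictors)
  }
}

#' Covariate summary statistics for a two-class cohort table
#'
#' Reproduces the univariate clinical comparison layer: binary covariates
#' get a chi-squared test (Pearson; Yates when any expected count is below
#' 5; Fisher's exact when below 1), continuous covariates go through
#' [group_compare()].
#'
#' @param data data.frame with `label` and covariates.
#' @param binary_covariates,continuous_covariates column name vectors.
#' @return data.frame with `covariate`, `statistic`, `method`, `p`.
#' @export
clinical_summary <- function(data, binary_covariates = character(),
                             continuous_covariates = character()) {
  y <- as.factor(data$label)
  rows <- list()
  for (v in binary_covariates) {
    tb <- table(factor(data[[v]], levels = 0:1), y)
    expected <- outer(rowSums(tb), colSums(tb)) / sum(tb)
    res <- if (any(expected < 1)) fisher_exact(tb)
    else if (any(expected < 5)) pearson_chi2(tb, "yates")
    else pearson_chi2(tb, "none")
    rows[[v]] <- data.frame(covariate = v, statistic = res$statistic,
                            method = res$method, p = res$p)
  }
  for (v in continuous_covariates) {
    res <- group_compare(data[[v]], y)
    rows[[v]] <- data.frame(covariate = v, statistic = res$statistic,
                            method = res$method, p = res$p)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
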