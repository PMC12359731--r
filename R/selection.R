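#' Selection-chain configuration
#'
#' @param icc_threshold minimum ICC(2,1) for a feature to pass the stability
#'   filter (default 0.75, conventional "good" reliability).
#' @param mrmr_keep number of features kept by the mRMR ranking (default 30).
#' @param lasso_folds folds for the cross-validated LASSO (default 10).
#' @param lambda_rule `"min"` (minimum mean CV deviance, default) or `"1se"`.
#' @param cor_prefilter if not `NULL`, drop one of any feature pair with
#'   absolute Pearson correlation above this value before mRMR (off by
#'   default; redundancy is otherwise handled inside mRMR).
#' @param seed integer seed controlling fold assignment.
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(icc_threshold = 0.75, mrmr_keep = 30,
                             lasso_folds = 10, lambda_rule = c("min", "1se"),
                             cor_prefilter = NULL, seed = 1L) {
  lambda_rule <- match.arg(lambda_rule)
  if (icc_threshold <= 0 || icc_threshold > 1)
    stop("`icc_threshold` must be in (0, 1]")
  if (lasso_folds < 2) stop("need at least 2 folds")
  if (mrmr_keep < 1) stop("`mrmr_keep` must be >= 1")
  structure(list(icc_threshold = icc_threshold, mrmr_keep = mrmr_keep,
                 lasso_folds = lasso_folds, lambda_rule = lambda_rule,
                 cor_prefilter = cor_prefilter, seed = as.integer(seed)),
            class = "selection_config")
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single rater, from the
#' standard ANOVA mean-squares decomposition:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#' If the ratings have zero total variance (identical constants) the ICC is
#' defined as 1.
#'
#' @param ratings numeric matrix, n subjects x k raters (n >= 3, k >= 2).
#' @return ICC estimate (scalar).
#' @export
icc_2_1 <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 3 || k < 2) stop("need at least 3 subjects and 2 raters")
  if (anyNA(ratings)) stop("ratings must be complete")
  grand <- mean(ratings)
  if (all(ratings == ratings[1])) return(1)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((ratings - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Inter-rater stability filter
#'
#' Keeps the features whose ICC(2,1) across two raters' extractions meets
#' the threshold. The two tables must have identical feature columns and
#' identically ordered case ids.
#'
#' @param features_rater1,features_rater2 numeric matrices (cases x
#'   features) with matching dimnames.
#' @param threshold minimum ICC (default 0.75).
#' @return Character vector of retained feature names, with the per-feature
#'   ICCs as attribute `icc`.
#' @export
stability_filter <- function(features_rater1, features_rater2,
                             threshold = 0.75) {
  f1 <- as.matrix(features_rater1)
  f2 <- as.matrix(features_rater2)
  if (!identical(colnames(f1), colnames(f2)))
    stop("feature columns differ between raters")
  if (!identical(rownames(f1), rownames(f2)))
    stop("case ids differ between raters")
  if (!identical(dim(f1), dim(f2))) stop("tables are misaligned")
  icc <- vapply(seq_len(ncol(f1)), function(j)
    icc_2_1(cbind(f1[, j], f2[, j])), numeric(1))
  names(icc) <- colnames(f1)
  keep <- colnames(f1)[icc >= threshold]
  attr(keep, "icc") <- icc
  keep
}

#' Minimum-redundancy maximum-relevance feature ranking
#'
#' Greedy MID (difference) scheme on standardized features: relevance is
#' the one-way ANOVA F statistic of the feature against the binary class,
#' mapped through `F / (F + n - 2)` (the squared point-biserial
#' correlation) so it shares the \[0, 1\] scale of the redundancy term;
#' redundancy is the mean absolute Pearson correlation with the
#' already-selected features; each step adds the feature maximizing
#' relevance minus redundancy. Ties break by feature name order. A
#' duplicated column is never picked right after its twin: its redundancy
#' of 1 outweighs any relevance.
#'
#' @param X numeric matrix (cases x features) with column names.
#' @param y binary labels.
#' @param k number of features to select; if `k > ncol(X)` all features are
#'   returned with a warning.
#' @return Character vector of selected names, in selection order.
#' @export
mrmr_select <- function(X, y, k = 30) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("X needs column names")
  y <- as.integer(as.factor(y))
  if (length(unique(y)) != 2) stop("y must be binary")
  if (k > ncol(X)) {
    warning("k exceeds the number of features; returning all")
    k <- ncol(X)
  }
  sds <- apply(X, 2, stats::sd)
  Xs <- X
  Xs[, sds > 0] <- scale(X[, sds > 0, drop = FALSE])
  Xs[, sds == 0] <- 0
  f <- f_stat_binary(Xs, y)
  relevance <- f / (f + length(y) - 2) # squared point-biserial correlation
  sel <- character(0)
  remaining <- colnames(X)
  # redundancy accumulates as a running sum of |cor| with selected features
  red_sum <- setNames(numeric(ncol(X)), colnames(X))
  for (step in seq_len(k)) {
    score <- relevance[remaining] -
      if (length(sel)) red_sum[remaining] / length(sel) else 0
    best <- remaining[order(-score, remaining)][1]
    sel <- c(sel, best)
    remaining <- setdiff(remaining, best)
    if (length(remaining)) {
      r <- abs(suppressWarnings(
        stats::cor(Xs[, remaining, drop = FALSE], Xs[, best])))
      r[!is.finite(r)] <- 0
      red_sum[remaining] <- red_sum[remaining] + r
    }
  }
  sel
}

# Vectorized one-way ANOVA F statistic for a binary grouping.
f_stat_binary <- function(X, y) {
  g <- split(seq_along(y), y)
  n1 <- length(g[[1]]); n2 <- length(g[[2]]); n <- n1 + n2
  m1 <- colMeans(X[g[[1]], , drop = FALSE])
  m2 <- colMeans(X[g[[2]], , drop = FALSE])
  m <- colMeans(X)
  ssb <- n1 * (m1 - m)^2 + n2 * (m2 - m)^2
  ssw <- colSums((X[g[[1]], , drop = FALSE] -
                    matrix(m1, n1, ncol(X), byrow = TRUE))^2) +
    colSums((X[g[[2]], , drop = FALSE] -
               matrix(m2, n2, ncol(X), byrow = TRUE))^2)
  f <- (ssb / 1) / (ssw / (n - 2))
  f[!is.finite(f)] <- 0
  setNames(f, colnames(X))
}

#' Cross-validated LASSO logistic regression radiomics signature
#'
#' L1-penalized logistic regression over a log-spaced lambda path with
#' stratified, seeded cross-validation folds; lambda is chosen at the
#' minimum mean CV binomial deviance (or the one-standard-error rule).
#' Columns are standardized internally; coefficients are reported on the
#' original feature scale. Constant columns are dropped with a warning.
#'
#' @param X numeric matrix (cases x features) with column and row names.
#' @param y binary labels (factor or 0/1); the second factor level is the
#'   positive class.
#' @param cfg a [selection_config].
#' @param roi_kind optional label stored in the model (e.g. "GTV").
#' @return An object of class `radscore_model`: selected feature names,
#'   `coefficients`, `intercept`, `lambda`, `lambda_rule`, `foldid`, `seed`.
#' @export
lasso_cv <- function(X, y, cfg = selection_config(), roi_kind = NULL) {
  X <- as.matrix(X)
  yf <- as.factor(y)
  if (nlevels(yf) != 2) stop("y must have exactly two classes")
  yb <- as.integer(yf) - 1L
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant columns: ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  ids <- rownames(X) %||% as.character(seq_len(nrow(X)))
  foldid <- stratified_folds(ids, yb, k = cfg$lasso_folds, seed = cfg$seed)
  cvfit <- glmnet::cv.glmnet(X, yb, family = "binomial", alpha = 1,
                             foldid = foldid, standardize = TRUE,
                             type.measure = "deviance")
  lam <- if (cfg$lambda_rule == "min") cvfit$lambda.min else cvfit$lambda.1se
  cf <- as.matrix(stats::coef(cvfit, s = lam))
  nz <- rownames(cf)[-1][cf[-1, 1] != 0]
  structure(list(
    roi_kind = roi_kind,
    features = nz,
    coefficients = setNames(cf[-1, 1][cf[-1, 1] != 0], nz),
    intercept = cf[1, 1],
    lambda = lam,
    lambda_rule = cfg$lambda_rule,
    foldid = setNames(foldid, ids),
    seed = cfg$seed,
    levels = levels(yf)), class = "radscore_model")
}

#' @export
print.radscore_model <- function(x, ...) {
  cat(sprintf("<radscore_model%s> %d features, lambda = %.4g (%s)\n",
              if (is.null(x$roi_kind)) "" else paste0(" ", x$roi_kind),
              length(x$features), x$lambda, x$lambda_rule))
  invisible(x)
}

#' Radiomics score (Radscore) of a fitted signature
#'
#' `inverse-logit(intercept + sum(coef * feature))`: the signature's
#' predicted probability of the positive class, in \[0, 1\]. The linear
#' predictor is available with `type = "link"`.
#'
#' @param model a `radscore_model`.
#' @param features named numeric vector, or matrix/data.frame with named
#'   columns, containing at least the model's selected features.
#' @param type `"response"` (probability, default) or `"link"`.
#' @return Numeric vector of scores.
#' @export
radscore <- function(model, features, type = c("response", "link")) {
  type <- match.arg(type)
  stopifnot(inherits(model, "radscore_model"))
  if (is.vector(features)) features <- t(as.matrix(features))
  features <- as.matrix(features)
  missing <- setdiff(model$features, colnames(features))
  if (length(missing))
    stop("missing selected features: ", paste(missing, collapse = ", "))
  eta <- model$intercept +
    as.numeric(features[, model$features, drop = FALSE] %*%
                 model$coefficients)
  if (type == "link") eta else stats::plogis(eta)
}

#' Serialize / restore a radscore model as JSON
#'
#' @param model a `radscore_model`.
#' @param path output (input) JSON path.
#' @return `path` invisibly; `read_radscore_model` returns the model.
#' @export
write_radscore_model <- function(model, path) {
  stopifnot(inherits(model, "radscore_model"))
  obj <- unclass(model)
  obj$foldid <- as.list(obj$foldid)
  obj$coefficients <- as.list(obj$coefficients)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_radscore_model
#' @export
read_radscore_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$coefficients <- unlist(obj$coefficients)
  obj$foldid <- unlist(obj$foldid)
  structure(obj, class = "radscore_model")
}
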