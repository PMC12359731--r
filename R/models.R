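#' Predictive models: CT-features and single-Radscore logistic fits
#'
#' The two model families are deliberately kept in separate frameworks: the
#' CT-features model uses only the maximum diameter and the vessel
#' convergence sign; each Radscore model uses only its single Radscore.
#' Fitting is maximum-likelihood logistic regression (IRLS via
#' `stats::glm`). Complete or quasi-complete separation is detected from
#' divergent coefficients and flagged in the returned object.
#'
#' @param data data.frame with a binary `label` column (second level is the
#'   positive class) and the predictor columns.
#' @param diameter_col,vcs_col predictor column names for the CT model.
#' @return A list of class `predictive_model`: `name`, `predictors`,
#'   `coefficients`, `fitted` (per-case probabilities), `separation` flag,
#'   and the underlying `glm` fit.
#' @export
fit_ct_model <- function(data, diameter_col = "max_diameter_mm",
                         vcs_col = "vcs") {
  if (!all(c(diameter_col, vcs_col, "label") %in% names(data)))
    stop("missing columns: need label, ", diameter_col, ", ", vcs_col)
  fit_logistic_model(data, c(diameter_col, vcs_col), name = "CTfeatures")
}

#' @rdname fit_ct_model
#' @param radscore_col name of the single Radscore column.
#' @param name model name (default the Radscore column).
#' @export
fit_radscore_model <- function(data, radscore_col, name = radscore_col) {
  if (!all(c(radscore_col, "label") %in% names(data)))
    stop("missing columns: need label, ", radscore_col)
  fit_logistic_model(data, radscore_col, name = name)
}

fit_logistic_model <- function(data, predictors, name) {
  y <- as.factor(data$label)
  if (nlevels(y) != 2) stop("label must be binary")
  keep <- vapply(predictors, function(p) stats::sd(data[[p]]) > 0, logical(1))
  form <- if (any(keep))
    stats::reformulate(predictors[keep], response = "label_bin")
  else stats::as.formula("label_bin ~ 1")
  df <- data
  df$label_bin <- as.integer(y) - 1L
  fit <- suppressWarnings(
    stats::glm(form, family = stats::binomial(), data = df,
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  separation <- !fit$converged || any(abs(stats::coef(fit)[-1]) > 20)
  structure(list(name = name, predictors = predictors,
                 coefficients = stats::coef(fit),
                 fitted = as.numeric(stats::fitted(fit)),
                 separation = separation, glm = fit,
                 levels = levels(y)), class = "predictive_model")
}

#' @export
print.predictive_model <- function(x, ...) {
  cat(sprintf("<predictive_model %s> predictors: %s%s\n", x$name,
              paste(x$predictors, collapse = ", "),
              if (x$separation) " [separation flagged]" else ""))
  print(signif(x$coefficients, 4))
  invisible(x)
}

#' Predict probabilities from a predictive model
#'
#' @param object a `predictive_model`.
#' @param newdata data.frame with the predictor columns; omit for fitted
#'   values.
#' @param ... unused.
#' @return Numeric vector of probabilities of the positive class.
#' @export
predict.predictive_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  as.numeric(stats::predict(object$glm, newdata = newdata,
                            type = "response"))
}

#' Stratified out-of-fold cross-validated probabilities
#'
#' Refits the supplied model constructor on each training fold and predicts
#' the held-out fold, so every case receives exactly one out-of-fold
#' probability. Folds are stratified by class and derived from case ids and
#' the seed ([stratified_folds()]). If some training fold lacks both
#' classes, folds are redrawn with a shifted seed (error after 10 retries).
#'
#' @param data data.frame with `label`, a `case_id` column (created from row
#'   numbers if absent), and predictors.
#' @param fit_fun function(data) returning a `predictive_model`.
#' @param folds number of folds (default 10).
#' @param seed integer seed.
#' @return data.frame `case_id`, `fold`, `probability`, ordered as `data`.
#' @export
crossvalidate <- function(data, fit_fun, folds = 10, seed = 1L) {
  if (folds < 2) stop("need at least 2 folds")
  ids <- if ("case_id" %in% names(data)) as.character(data$case_id)
  else sprintf("row%04d", seq_len(nrow(data)))
  y <- as.integer(as.factor(data$label)) - 1L
  for (try in 0:9) {
    fold <- stratified_folds(ids, y, k = folds, seed = seed + try)
    ok <- all(vapply(seq_len(folds), function(f)
      length(unique(y[fold != f])) == 2, logical(1)))
    if (ok) break
    if (try == 9) stop("could not build folds with both classes in training")
  }
  prob <- numeric(nrow(data))
  for (f in seq_len(folds)) {
    test <- fold == f
    if (!any(test)) next
    m <- fit_fun(data[!test, , drop = FALSE])
    prob[test] <- predict(m, newdata = data[test, , drop = FALSE])
  }
  data.frame(case_id = ids, fold = fold, probability = prob,
             stringsAsFactors = FALSE)
}
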