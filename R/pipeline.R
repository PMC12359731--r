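#' Extract the feature table for a whole cohort
#'
#' For each case, builds the GTV/GPTV/GPR triplet (after resampling to the
#' configured target spacing when needed) and extracts all configured
#' features per region. Optionally repeats the extraction with a boundary-
#' perturbed mask emulating a second rater ([perturb_mask()]), for the ICC
#' stability filter.
#'
#' @param cohort a `synthetic_cohort` (or a list with `cases` of
#'   `synthetic_case` and a `clinical` data.frame).
#' @param prep a [preprocess_config].
#' @param cfg a [feature_config].
#' @param raters 1 or 2.
#' @param margin_mm peritumoral margin (default 5 mm).
#' @return A list with one element per ROI (`GTV`, `GPTV`, `GPR`), each a
#'   numeric matrix cases x features with case-id rownames; with
#'   `raters = 2` also `rater2`, the same structure for the perturbed
#'   masks.
#' @export
cohort_features <- function(cohort, prep = preprocess_config(),
                            cfg = feature_config(), raters = 1,
                            margin_mm = 5) {
  ids <- as.character(cohort$clinical$case_id)
  one_rater <- function(perturb) {
    per_case <- lapply(seq_along(cohort$cases), function(i) {
      cs <- cohort$cases[[i]]
      img <- cs$image
      mask <- cs$gtv_mask
      if (!isTRUE(all.equal(img$spacing, prep$target_spacing_mm))) {
        img <- resample_volume(img, prep)
        mask <- resample_mask(volume_image(mask * 1, cs$image$spacing,
                                           cs$image$origin), prep)$values > 0
      }
      if (perturb)
        mask <- perturb_mask(mask, rate = 0.2,
                             seed = cs$seed_used %% 2000000011 + 1)
      trip <- suppressWarnings(build_roi_triplet(mask, img$spacing, margin_mm))
      extract_all(img, trip, prep, cfg)
    })
    lapply(c(GTV = "GTV", GPTV = "GPTV", GPR = "GPR"), function(roi) {
      m <- do.call(rbind, lapply(per_case, `[[`, roi))
      rownames(m) <- ids
      m
    })
  }
  out <- one_rater(FALSE)
  if (raters == 2) out$rater2 <- one_rater(TRUE)
  out
}

#' Run the Radscore construction chain for one ROI
#'
#' The three-stage reduction: ICC(2,1) stability filter (when a second
#' rater's table is supplied), mRMR ranking, and cross-validated LASSO
#' logistic regression; the Radscore is the signature's predicted
#' probability.
#'
#' @param X cases x features matrix for the ROI (rater 1).
#' @param y binary labels.
#' @param cfg a [selection_config].
#' @param X2 optional rater-2 matrix for the stability filter.
#' @param roi_kind stored in the model.
#' @return A list: `model` (`radscore_model`), `radscore` (per-case score),
#'   `kept_stable`, `kept_mrmr`.
#' @export
build_radscore <- function(X, y, cfg = selection_config(), X2 = NULL,
                           roi_kind = NULL) {
  keep <- colnames(X)
  if (!is.null(X2)) keep <- stability_filter(X, X2, cfg$icc_threshold)
  if (length(keep) < 2) stop("stability filter left fewer than 2 features")
  Xk <- X[, keep, drop = FALSE]
  if (!is.null(cfg$cor_prefilter)) {
    Xk <- drop_correlated(Xk, cfg$cor_prefilter)
  }
  sel <- mrmr_select(Xk, y, k = min(cfg$mrmr_keep, ncol(Xk)))
  model <- lasso_cv(Xk[, sel, drop = FALSE], y, cfg, roi_kind = roi_kind)
  list(model = model, radscore = radscore(model, Xk),
       kept_stable = keep, kept_mrmr = sel)
}

# Drop one of each pair with |r| > threshold (keeps the first by name order).
drop_correlated <- function(X, threshold) {
  cm <- abs(suppressWarnings(stats::cor(X)))
  cm[!is.finite(cm)] <- 0
  diag(cm) <- 0
  keep <- rep(TRUE, ncol(X))
  ord <- order(colnames(X))
  for (i in ord) {
    if (!keep[i]) next
    keep[cm[, i] > threshold & seq_len(ncol(X)) != i &
           rank(colnames(X)) > rank(colnames(X))[i]] <- FALSE
  }
  X[, keep, drop = FALSE]
}

#' Out-of-fold Radscore probabilities by nested cross-validation
#'
#' The honest cross-validated performance of a Radscore model: within each
#' training fold the whole selection chain (mRMR ranking and LASSO) is
#' refit and the held-out cases are scored with the fold's signature. The
#' stability filter, which uses no labels, is applied once up front.
#'
#' @inheritParams build_radscore
#' @param folds outer folds (default 10).
#' @param seed integer seed for the outer folds.
#' @return Numeric vector of out-of-fold probabilities aligned with the
#'   rows of `X`.
#' @export
radscore_cv <- function(X, y, cfg = selection_config(), X2 = NULL,
                        folds = 10, seed = 1L) {
  keep <- colnames(X)
  if (!is.null(X2)) keep <- stability_filter(X, X2, cfg$icc_threshold)
  Xk <- X[, keep, drop = FALSE]
  ids <- rownames(Xk) %||% as.character(seq_len(nrow(Xk)))
  yb <- as.integer(as.factor(y)) - 1L
  fold <- stratified_folds(ids, yb, k = folds, seed = seed)
  prob <- numeric(nrow(Xk))
  for (f in seq_len(folds)) {
    test <- fold == f
    sel <- mrmr_select(Xk[!test, , drop = FALSE], yb[!test],
                       k = min(cfg$mrmr_keep, ncol(Xk)))
    inner_cfg <- cfg
    inner_cfg$seed <- cfg$seed + f
    model <- lasso_cv(Xk[!test, sel, drop = FALSE], yb[!test], inner_cfg)
    prob[test] <- radscore(model, Xk[test, , drop = FALSE])
  }
  prob
}

#' Run the full comparative study on a cohort
#'
#' Builds the four predictive models (GTV, GPTV and GPR Radscores, each in
#' its own framework, and the CT-features model on maximum diameter + VCS),
#' evaluates apparent (resubstitution) and out-of-fold cross-validated
#' discrimination, and produces the pairwise DeLong comparison table on the
#' apparent scores.
#'
#' @param cohort a `synthetic_cohort`.
#' @param sel a [selection_config].
#' @param prep a [preprocess_config].
#' @param cfg a [feature_config].
#' @param folds cross-validation folds (default 10).
#' @param raters 2 enables the ICC stability filter (default), 1 disables.
#' @return A list of class `study_result`: `radscore` (per-ROI scores),
#'   `models`, `auc_apparent`, `auc_cv`, `cv_prob`, `comparison`, `labels`.
#' @export
run_study <- function(cohort, sel = selection_config(),
                      prep = preprocess_config(), cfg = feature_config(),
                      folds = 10, raters = 2) {
  feats <- cohort_features(cohort, prep, cfg, raters = raters)
  y <- cohort$clinical$label
  rois <- c("GTV", "GPTV", "GPR")
  scores <- list()
  cv_prob <- list()
  models <- list()
  for (roi in rois) {
    X2 <- if (raters == 2) feats$rater2[[roi]] else NULL
    br <- build_radscore(feats[[roi]], y, sel, X2 = X2, roi_kind = roi)
    models[[roi]] <- br$model
    scores[[roi]] <- br$radscore
    cv_prob[[roi]] <- radscore_cv(feats[[roi]], y, sel, X2 = X2,
                                  folds = folds, seed = sel$seed)
  }
  ct <- fit_ct_model(cohort$clinical)
  models$CTfeatures <- ct
  scores$CTfeatures <- ct$fitted
  cv_prob$CTfeatures <- crossvalidate(cohort$clinical, fit_ct_model,
                                      folds = folds,
                                      seed = sel$seed)$probability
  auc_of <- function(s) roc_auc(s, y)$auc
  structure(list(
    radscore = scores, models = models,
    auc_apparent = vapply(scores, auc_of, numeric(1)),
    auc_cv = vapply(cv_prob, auc_of, numeric(1)),
    cv_prob = cv_prob,
    comparison = compare_models(scores, y),
    labels = y), class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat("<study_result>\n  apparent AUC: ",
      paste(sprintf("%s %.3f", names(x$auc_apparent), x$auc_apparent),
            collapse = ", "),
      "\n  out-of-fold AUC: ",
      paste(sprintf("%s %.3f", names(x$auc_cv), x$auc_cv), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
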