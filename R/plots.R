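#' Plot methods for evaluation objects
#'
#' Base-graphics plots: the empirical ROC curve (with the Youden-optimal
#' operating point marked), the calibration scatter of observed versus mean
#' predicted event rates per risk bin, and the decision curves with the
#' treat-all and treat-none references.
#'
#' @param x a `roc_result`, `calibration_result` or `decision_curve`.
#' @param ... passed to the underlying plot call.
#' @return The input, invisibly.
#' @name evaluation-plots
NULL

#' @rdname evaluation-plots
#' @export
plot.roc_result <- function(x, ...) {
  fpr <- c(1, 1 - x$specificity, 0)
  tpr <- c(1, x$sensitivity, 0)
  graphics::plot(fpr, tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "1 - specificity", ylab = "Sensitivity",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey")
  i <- which(x$thresholds == x$youden_cutoff)
  graphics::points(1 - x$specificity[i], x$sensitivity[i], pch = 19)
  invisible(x)
}

#' @rdname evaluation-plots
#' @export
plot.calibration_result <- function(x, ...) {
  obs <- x$bins$observed / x$bins$n
  graphics::plot(x$bins$mean_predicted, obs, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "Mean predicted probability",
                 ylab = "Observed event rate",
                 main = sprintf("Calibration (HL p = %.3f)", x$p), pch = 19,
                 ...)
  graphics::abline(0, 1, lty = 3, col = "grey")
  invisible(x)
}

#' @rdname evaluation-plots
#' @export
plot.decision_curve <- function(x, ...) {
  ylim <- range(c(x$net_benefit, x$treat_all, 0), finite = TRUE)
  graphics::plot(x$p_t, x$net_benefit, type = "l", ylim = ylim,
                 xlab = "Threshold probability", ylab = "Net benefit",
                 main = "Decision curve", ...)
  graphics::lines(x$p_t, x$treat_all, lty = 2, col = "grey40")
  graphics::abline(h = 0, lty = 3, col = "grey")
  graphics::legend("topright", bty = "n", lty = c(1, 2, 3),
                   col = c("black", "grey40", "grey"),
                   legend = c("model", "treat all", "treat none"))
  invisible(x)
}
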