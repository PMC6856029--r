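#' Coefficient of determination for binary-outcome regression scores
#'
#' Computes `1 - SS_res / SS_tot` for continuous predictions of a 0/1
#' outcome. Used both as R2 (fit on the full training data) and as Q2
#' (pooled cross-validated predictions); for Q2 the denominator mean should
#' be the full training-set mean, supplied via `ss_tot_mean`.
#'
#' @param y Binary 0/1 outcome vector, not constant.
#' @param y_star Continuous score vector of the same length.
#' @param ss_tot_mean Mean used in the total sum of squares; defaults to
#'   `mean(y)`.
#' @return A scalar `<= 1`, unbounded below.
#' @export
#' @examples
#' coefficient_of_determination(c(0, 1, 1, 0), c(0.25, 0.75, 0.75, 0.25))
coefficient_of_determination <- function(y, y_star, ss_tot_mean = mean(y)) {
  stopifnot(length(y) == length(y_star), length(y) >= 2)
  if (length(unique(y)) < 2) {
    stop_metabench("Outcome is constant; R2 is undefined.",
                   "metabench_metric_error")
  }
  ss_res <- sum((y - y_star)^2)
  ss_tot <- sum((y - ss_tot_mean)^2)
  1 - ss_res / ss_tot
}

#' ROC curve from continuous scores
#'
#' Builds the receiver operating characteristic curve by sweeping a
#' threshold over the distinct score values (higher score = more likely
#' positive). Tied scores are grouped into a single step, so trapezoidal
#' integration of the curve reproduces the Mann-Whitney concordance
#' probability exactly, ties counting one half.
#'
#' @param y Binary 0/1 outcome vector with both classes present.
#' @param scores Continuous score vector.
#' @return A tibble of class `roc_curve` with columns `threshold`, `fpr`,
#'   `tpr`; starts at (0, 0) and ends at (1, 1), both coordinates
#'   non-decreasing.
#' @export
roc_curve <- function(y, scores) {
  check_roc_inputs(y, scores)
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]; scores <- scores[ord]
  keep <- !duplicated(scores)            # group tied thresholds
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- c(which(keep)[-1] - 1L, length(y))
  n1 <- sum(y); n0 <- length(y) - n1
  out <- tibble::tibble(
    threshold = c(Inf, scores[keep]),
    fpr = c(0, fp[last] / n0),
    tpr = c(0, tp[last] / n1)
  )
  class(out) <- c("roc_curve", class(out))
  out
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney concordance probability: the probability
#' that a random positive sample outscores a random negative one, tied
#' scores counting one half. Equal (to machine precision) to trapezoidal
#' integration of [roc_curve()].
#'
#' @inheritParams roc_curve
#' @return A scalar in \[0, 1\].
#' @export
#' @examples
#' auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))
auc <- function(y, scores) {
  check_roc_inputs(y, scores)
  n1 <- sum(y); n0 <- length(y) - n1
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Trapezoidal area under a ROC curve object
#'
#' @param roc A `roc_curve`.
#' @return The trapezoidal integral of TPR over FPR.
#' @export
auc_trapezoid <- function(roc) {
  n <- nrow(roc)
  sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-n]) / 2)
}

check_roc_inputs <- function(y, scores) {
  stopifnot(length(y) == length(scores))
  if (!is_binary01(y)) {
    stop_metabench("ROC/AUC need a 0/1 outcome with both classes present.",
                   "metabench_metric_error")
  }
  if (any(!is.finite(scores))) {
    stop_metabench("Scores must be finite.", "metabench_metric_error")
  }
  invisible(TRUE)
}

# Interpolate a ROC curve onto a fixed FPR grid (linear interpolation of the
# step curve between distinct-threshold vertices; used for bootstrap bands).
interpolate_roc <- function(roc, fpr_grid) {
  approx(roc$fpr, roc$tpr, xout = fpr_grid, ties = max,
         yleft = 0, yright = 1)$y
}

#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(intercept = 0, slope = 1, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate")
}
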