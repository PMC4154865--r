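# Empirical ROC analysis for the marker models: curve construction with
# positive calls at score >= threshold, trapezoidal AUC (Mann-Whitney with
# ties counted one half), unnormalized partial AUC over a specificity range,
# the operating point at the specificity closest to a target, and the DeLong
# placement-value test for the increase in AUC between two correlated models.

#' Empirical ROC curve
#'
#' One operating point per distinct score plus the two endpoints; a subject
#' is called positive when its score is at or above the threshold, so higher
#' scores must be more case-like.
#'
#' @param scores Numeric scores (e.g. predicted probabilities).
#' @param labels Vector with values `"case"` / `"control"` (or a logical
#'   vector, `TRUE` = case), same length as `scores`.
#' @return A `roc_curve`: data frame with columns `threshold`,
#'   `sensitivity`, `specificity`, ordered from the all-negative endpoint
#'   (sens 0, spec 1) to the all-positive endpoint (sens 1, spec 0);
#'   attributes `n_case` and `n_control`.
#' @export
empirical_roc <- function(scores, labels) {
  y <- as_case_logical(labels)
  if (length(scores) != length(y)) stop("length mismatch", call. = FALSE)
  if (!any(y) || all(y)) stop("need both cases and controls", call. = FALSE)
  cs <- scores[y]; ct <- scores[!y]
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) mean(cs >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(ct < t), numeric(1))
  out <- data.frame(threshold = thr, sensitivity = sens, specificity = spec)
  attr(out, "n_case") <- length(cs)
  attr(out, "n_control") <- length(ct)
  class(out) <- c("roc_curve", "data.frame")
  out
}

as_case_logical <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (all(labels %in% c("case", "control"))) return(labels == "case")
  if (all(labels %in% c(0, 1))) return(labels == 1)
  stop("labels must be case/control, logical, or 0/1", call. = FALSE)
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("Empirical ROC: %d operating points, %d cases / %d controls, AUC = %.4f\n",
              nrow(x), attr(x, "n_case"), attr(x, "n_control"), auc(x)))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Trapezoidal area, identical to the Mann-Whitney probability that a random
#' case outscores a random control with ties counted one half.
#'
#' @param curve A [empirical_roc()] result.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  fpr <- 1 - curve$specificity
  ord <- order(fpr, curve$sensitivity)
  x <- fpr[ord]; yv <- curve$sensitivity[ord]
  sum(diff(x) * (utils::head(yv, -1) + utils::tail(yv, -1)) / 2)
}

#' Partial AUC over a specificity range
#'
#' Unnormalized area of sensitivity integrated over specificity within
#' `spec_range`, with linear interpolation at the range boundaries; the
#' maximum achievable value equals the width of the range (0.10 for the
#' default 90-100% specificity band). McClish standardization to \[0.5, 1\]
#' is available via `standardize`.
#'
#' @param curve A `roc_curve`.
#' @param spec_range Two specificities `c(lo, hi)` with
#'   `0 <= lo < hi <= 1`.
#' @param standardize Report the McClish-standardized value instead of the
#'   raw area.
#' @return Raw area in `[0, hi - lo]` (or the standardized value).
#' @export
partial_auc <- function(curve, spec_range = c(0.90, 1.00),
                        standardize = FALSE) {
  stopifnot(inherits(curve, "roc_curve"))
  lo <- spec_range[1]; hi <- spec_range[2]
  if (!(lo >= 0 && lo < hi && hi <= 1))
    stop("invalid specificity range", call. = FALSE)
  # clipped trapezoid in false-positive-rate space: walk the curve's
  # segments, intersect each with the FPR window [1-hi, 1-lo], and
  # interpolate linearly at the window boundaries; vertical segments
  # (tied specificity) contribute zero width
  fpr <- 1 - curve$specificity
  ord <- order(fpr, curve$sensitivity)
  x <- fpr[ord]; yv <- curve$sensitivity[ord]
  a <- 1 - hi; b <- 1 - lo
  area <- 0
  for (k in seq_len(length(x) - 1L)) {
    x1 <- x[k]; x2 <- x[k + 1L]
    if (x2 <= a || x1 >= b || x1 == x2) next
    y_at <- function(s) yv[k] + (yv[k + 1L] - yv[k]) * (s - x1) / (x2 - x1)
    s1 <- max(x1, a); s2 <- min(x2, b)
    area <- area + (s2 - s1) * (y_at(s1) + y_at(s2)) / 2
  }
  if (standardize) 0.5 * (1 + (area - pauc_min(lo, hi)) /
                            ((hi - lo) - pauc_min(lo, hi)))
  else area
}

pauc_min <- function(lo, hi) {
  # area under the chance diagonal sens = 1 - spec over [lo, hi]
  (hi - lo) * (1 - (lo + hi) / 2)
}

#' Operating point at the specificity closest to a target
#'
#' Scans the achievable operating points (including endpoints) and returns
#' the one whose specificity minimizes the distance to `target`. Equidistant
#' candidates resolve to the higher specificity (the conservative screening
#' choice); among points sharing that specificity the highest sensitivity is
#' reported.
#'
#' @param curve A `roc_curve`.
#' @param target Target specificity in \[0, 1\] (default 0.90).
#' @return List with `sensitivity`, `specificity` (achieved) and
#'   `threshold`.
#' @export
sensitivity_at_spec_closest <- function(curve, target = 0.90) {
  stopifnot(inherits(curve, "roc_curve"), target >= 0, target <= 1)
  d <- abs(curve$specificity - target)
  cand <- which(d == min(d))
  cand <- cand[curve$specificity[cand] == max(curve$specificity[cand])]
  best <- cand[which.max(curve$sensitivity[cand])]
  list(sensitivity = curve$sensitivity[best],
       specificity = curve$specificity[best],
       threshold = curve$threshold[best])
}

# Placement values: for each case, the fraction of controls it beats
# (ties one half), and vice versa. The mean of either vector is the AUC.
placement_values <- function(scores, y) {
  cs <- scores[y]; ct <- scores[!y]
  psi <- outer(cs, ct, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi))
}

#' DeLong paired test for the increase in AUC
#'
#' Nonparametric comparison of two correlated AUCs computed from two score
#' vectors on the same subjects, using structural components (placement
#' values) to estimate the covariance. Reports each AUC with a 95% Wald CI,
#' the difference `auc_2 - auc_1`, its variance, the z statistic and the
#' two-sided normal p-value. If the variance of the difference degenerates
#' to zero the p-value is 1 when the difference is exactly zero and `NA`
#' otherwise.
#'
#' @param scores_1,scores_2 Score vectors for the two models, same subjects
#'   in the same order.
#' @param labels Case/control labels (see [empirical_roc()]).
#' @return A `delong_result` list: `auc_1`, `auc_2`, `ci_1`, `ci_2`,
#'   `delta`, `variance_delta`, `z`, `p_value`.
#' @export
delong_test <- function(scores_1, scores_2, labels) {
  y <- as_case_logical(labels)
  if (length(scores_1) != length(y) || length(scores_2) != length(y))
    stop("score vectors must match the labels", call. = FALSE)
  m <- sum(y); n <- sum(!y)
  if (m < 2 || n < 2) stop("need at least 2 cases and 2 controls",
                           call. = FALSE)
  p1 <- placement_values(scores_1, y)
  p2 <- placement_values(scores_2, y)
  a1 <- mean(p1$v10); a2 <- mean(p2$v10)
  s10 <- stats::cov(cbind(p1$v10, p2$v10))
  s01 <- stats::cov(cbind(p1$v01, p2$v01))
  var1 <- s10[1, 1] / m + s01[1, 1] / n
  var2 <- s10[2, 2] / m + s01[2, 2] / n
  var_d <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
           (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  delta <- a2 - a1
  if (var_d <= 0) {
    z <- if (delta == 0) 0 else NA_real_
    p <- if (delta == 0) 1 else NA_real_
  } else {
    z <- delta / sqrt(var_d)
    p <- 2 * stats::pnorm(-abs(z))
  }
  ci <- function(a, v) a + c(-1, 1) * stats::qnorm(0.975) * sqrt(max(v, 0))
  structure(list(auc_1 = a1, auc_2 = a2,
                 var_auc_1 = var1, var_auc_2 = var2,
                 ci_1 = ci(a1, var1), ci_2 = ci(a2, var2),
                 delta = delta, variance_delta = var_d,
                 z = z, p_value = p),
            class = "delong_result")
}

#' @export
print.delong_result <- function(x, ...) {
  cat(sprintf("DeLong paired AUC test\n  AUC1 = %.4f (%.4f-%.4f)\n  AUC2 = %.4f (%.4f-%.4f)\n  delta = %.4f, z = %s, p = %s\n",
              x$auc_1, x$ci_1[1], x$ci_1[2], x$auc_2, x$ci_2[1], x$ci_2[2],
              x$delta, format(x$z, digits = 4),
              format.pval(x$p_value, digits = 4)))
  invisible(x)
}

#' Export ROC operating points as CSV
#'
#' @param curve A `roc_curve`.
#' @param file Path to the CSV file (`threshold,sensitivity,specificity`).
#' @return The path, invisibly.
#' @export
write_roc_points <- function(curve, file) {
  stopifnot(inherits(curve, "roc_curve"))
  utils::write.csv(as.data.frame(curve), file, row.names = FALSE)
  invisible(file)
}
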