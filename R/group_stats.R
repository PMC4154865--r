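# Two-group and k-group comparisons used for the descriptive cohort table:
# Wilcoxon rank-sum, Kruskal-Wallis and Pearson chi-square, all reported as
# a uniform test_result. The computational engines are the base R tests
# (normal / chi-square approximations with midrank tie handling); this layer
# fixes the conventions (two-sided, no continuity correction by default) and
# the degenerate cases.

new_test_result <- function(statistic, p_value, method, n) {
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 method = method, n = n),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method, "\n  statistic =", format(x$statistic),
      " p =", format.pval(x$p_value, digits = 4),
      " n =", paste(x$n, collapse = "/"), "\n")
  invisible(x)
}

#' Wilcoxon rank-sum test (normal approximation, midranks)
#'
#' Two-sided two-sample rank-sum test with midranks for ties and the
#' tie-corrected normal approximation, without continuity correction. The
#' reported statistic is the rank sum of `x` in the pooled sample (the
#' Mann-Whitney U plus its minimum). When every pooled observation is tied
#' the statistic sits at its null mean and p = 1.
#'
#' @param x,y Non-empty numeric vectors.
#' @return A `test_result` with the rank-sum statistic, two-sided p-value
#'   and per-group sizes.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty",
                                     call. = FALSE)
  n1 <- length(x); n2 <- length(y)
  ranks <- rank(c(x, y))
  w <- sum(ranks[seq_len(n1)])
  pooled_sd <- stats::sd(c(x, y))
  if (!is.na(pooled_sd) && pooled_sd == 0) {
    p <- 1
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value)
    if (is.na(p)) p <- 1
  }
  new_test_result(w, p, "Wilcoxon rank-sum test (normal approximation)",
                  c(n1, n2))
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic compared to a chi-square distribution with
#' `k - 1` degrees of freedom. A completely tied sample gives H = 0, p = 1.
#'
#' @param groups List of two or more non-empty numeric vectors.
#' @return A `test_result`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  if (any(!lengths(groups))) stop("all groups must be non-empty",
                                  call. = FALSE)
  pooled <- unlist(groups, use.names = FALSE)
  if (length(unique(pooled)) == 1L)
    return(new_test_result(0, 1, "Kruskal-Wallis rank test", lengths(groups)))
  kt <- stats::kruskal.test(groups)
  new_test_result(kt$statistic, kt$p.value, "Kruskal-Wallis rank test",
                  lengths(groups))
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson X-squared with `(r-1)(k-1)` degrees of freedom; Yates continuity
#' correction is off by default (available for 2x2 tables via `correct`).
#'
#' @param table Matrix of non-negative integer counts with positive row and
#'   column margins.
#' @param correct Apply the continuity correction (2x2 only).
#' @return A `test_result`; `n` holds the row margins.
#' @export
pearson_chi_square <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero row or column margin", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(table, correct = correct))
  new_test_result(ct$statistic, ct$p.value, "Pearson chi-square test",
                  rowSums(table))
}
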