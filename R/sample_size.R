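# Exact-binomial design calculations for diagnostic accuracy studies:
# Clopper-Pearson lower confidence limits, the assurance probability that
# the observed limit will clear a floor given a true sensitivity or
# specificity, the smallest n achieving a target assurance, and dropout
# inflation.

#' Exact (Clopper-Pearson) lower confidence limit for a proportion
#'
#' The lower bound obtained by inverting the binomial tail, computed through
#' the beta quantile: `qbeta(alpha, k, n - k + 1)` with `alpha = 1 -
#' confidence` (one-sided) or `(1 - confidence)/2` (two-sided). `k = 0`
#' returns 0.
#'
#' @param k Number of successes, `0 <= k <= n` (vectorized).
#' @param n Number of trials.
#' @param confidence Confidence level (default 0.95).
#' @param sided `"one"` or `"two"`.
#' @return Lower limit(s) in \[0, 1).
#' @export
exact_lower_limit <- function(k, n, confidence = 0.95,
                              sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (any(k < 0) || any(k > n) || any(k != round(k)) || n < 1)
    stop("need integer 0 <= k <= n", call. = FALSE)
  alpha <- if (sided == "one") 1 - confidence else (1 - confidence) / 2
  ifelse(k == 0, 0, stats::qbeta(alpha, k, n - k + 1))
}

#' Assurance probability for an exact lower confidence limit
#'
#' Probability, under `Binomial(n, true_value)`, that the exact lower
#' confidence limit of the observed proportion exceeds `lower_limit`.
#' Computed by exact enumeration over k = 0..n; deterministic.
#'
#' @param n Number of subjects.
#' @param true_value True sensitivity or specificity in (0, 1).
#' @param lower_limit Floor the lower limit must exceed,
#'   `0 < lower_limit < true_value`.
#' @param confidence Confidence level of the limit.
#' @param sided Sidedness of the limit (default one-sided).
#' @return Probability in \[0, 1\].
#' @export
assurance_probability <- function(n, true_value, lower_limit,
                                  confidence = 0.95,
                                  sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (!(lower_limit > 0 && lower_limit < true_value && true_value < 1))
    stop("need 0 < lower_limit < true_value < 1", call. = FALSE)
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  k <- 0:n
  low <- exact_lower_limit(k, n, confidence, sided)
  sum(stats::dbinom(k, n, true_value)[low > lower_limit])
}

#' Smallest n reaching a target assurance
#'
#' Scans n upward until `assurance_probability(n, ...) >= assurance`.
#' Because the exact-binomial assurance is saw-toothed in n, the returned
#' value carries an attribute `stable`: `TRUE` when the assurance also holds
#' for the next `window` sample sizes, `FALSE` when it dips back below
#' (reported honestly rather than smoothed away).
#'
#' @param true_value,lower_limit,confidence,sided As in
#'   [assurance_probability()].
#' @param assurance Target probability in (0, 1).
#' @param cap Largest n to consider.
#' @param window Number of subsequent sample sizes checked for stability.
#' @return Integer n with attribute `stable`; errors if the cap is reached
#'   without a solution.
#' @export
required_n <- function(true_value, lower_limit, assurance,
                       confidence = 0.95, sided = c("one", "two"),
                       cap = 5000L, window = 25L) {
  sided <- match.arg(sided)
  if (!(assurance > 0 && assurance < 1))
    stop("assurance must lie in (0, 1)", call. = FALSE)
  for (n in seq_len(cap)) {
    if (assurance_probability(n, true_value, lower_limit, confidence,
                              sided) >= assurance) {
      later <- vapply(n + seq_len(window), assurance_probability,
                      numeric(1), true_value = true_value,
                      lower_limit = lower_limit, confidence = confidence,
                      sided = sided)
      out <- n
      attr(out, "stable") <- all(later >= assurance)
      return(out)
    }
  }
  stop("no n up to cap = ", cap, " reaches the target assurance",
       call. = FALSE)
}

#' Inflate a sample size for expected dropout
#'
#' Smallest integer m with `m * (1 - dropout_rate) >= n` (ceiling rule), so
#' the expected post-dropout count still meets the design n.
#'
#' @param n Required evaluable subjects.
#' @param dropout_rate Expected dropout proportion, `0 <= rate < 1`.
#' @return Integer m.
#' @export
inflate_for_dropout <- function(n, dropout_rate) {
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must lie in [0, 1)", call. = FALSE)
  if (n < 0 || n != round(n)) stop("n must be a non-negative integer",
                                   call. = FALSE)
  m <- ceiling(n / (1 - dropout_rate))
  # guard against floating-point overshoot at exact multiples
  while (m > 0 && (m - 1) * (1 - dropout_rate) >= n) m <- m - 1
  as.integer(m)
}
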