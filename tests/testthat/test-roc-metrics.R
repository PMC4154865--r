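# Independent oracle used throughout: the O(n^2) pairwise Mann-Whitney sum.
pairwise_auc <- function(scores, labels) {
  cs <- scores[labels == "case"]
  ct <- scores[labels == "control"]
  mean(outer(cs, ct, function(a, b) (a > b) + 0.5 * (a == b)))
}

test_that("ROC construction matches direct counting at every threshold", {
  expect_error(empirical_roc(1:4, rep("case", 4)), "both")
  set.seed(11)
  scores <- round(rnorm(20), 1)
  labels <- rep(c("case", "control"), each = 10)
  curve <- empirical_roc(scores, labels)
  # endpoints present
  expect_true(any(curve$sensitivity == 0 & curve$specificity == 1))
  expect_true(any(curve$sensitivity == 1 & curve$specificity == 0))
  # brute-force counting oracle at every threshold
  for (i in seq_len(nrow(curve))) {
    t <- curve$threshold[i]
    expect_equal(curve$sensitivity[i],
                 mean(scores[labels == "case"] >= t))
    expect_equal(curve$specificity[i],
                 mean(scores[labels == "control"] < t))
  }
  # lowering the threshold never lowers sensitivity or raises specificity
  ord <- order(curve$threshold, decreasing = TRUE)
  expect_true(all(diff(curve$sensitivity[ord]) >= -1e-12))
  expect_true(all(diff(curve$specificity[ord]) <= 1e-12))
})

test_that("AUC equals the pairwise oracle exactly, including ties", {
  labels <- rep(c("case", "control"), each = 8)
  # perfect separation
  expect_equal(auc(empirical_roc(c(9:16, 1:8), labels)), 1)
  # all scores equal: chance
  expect_equal(auc(empirical_roc(rep(1, 16), labels)), 0.5)
  set.seed(12)
  for (i in 1:25) {
    scores <- sample(round(rnorm(16), 1))
    expect_equal(auc(empirical_roc(scores, labels)),
                 pairwise_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUC is invariant to strictly monotone score transforms", {
  set.seed(13)
  scores <- rexp(30)
  labels <- rep(c("case", "control"), 15)
  a <- auc(empirical_roc(scores, labels))
  expect_equal(auc(empirical_roc(log(scores + 1), labels)), a)
  expect_equal(auc(empirical_roc(scores^3, labels)), a)
})

test_that("partial AUC hits the analytic bounds and is additive", {
  labels <- rep(c("case", "control"), each = 10)
  perfect <- empirical_roc(c(11:20, 1:10), labels)
  expect_equal(partial_auc(perfect, c(0.9, 1.0)), 0.10)
  chance <- empirical_roc(rep(1, 20), labels)
  expect_equal(partial_auc(chance, c(0.9, 1.0)), 0.005)
  expect_error(partial_auc(perfect, c(0.9, 0.9)), "invalid")

  set.seed(14)
  curve <- empirical_roc(round(rnorm(40), 1), rep(c("case", "control"), 20))
  expect_equal(partial_auc(curve, c(0.9, 0.95)) +
                 partial_auc(curve, c(0.95, 1.0)),
               partial_auc(curve, c(0.9, 1.0)), tolerance = 1e-12)
  # the full specificity range recovers the ordinary AUC
  expect_equal(partial_auc(curve, c(0, 1)), auc(curve), tolerance = 1e-12)
  # standardized value maps chance to 0.5 and the maximum to 1
  expect_equal(partial_auc(chance, c(0.9, 1), standardize = TRUE), 0.5)
  expect_equal(partial_auc(perfect, c(0.9, 1), standardize = TRUE), 1)
})

test_that("the operating point closest to the target specificity is selected", {
  set.seed(15)
  scores <- round(runif(60), 2)
  labels <- rep(c("case", "control"), 30)
  curve <- empirical_roc(scores, labels)
  for (target in c(0, 0.5, 0.9, 1)) {
    op <- sensitivity_at_spec_closest(curve, target)
    d <- abs(curve$specificity - target)
    expect_equal(abs(op$specificity - target), min(d))
    # exhaustive-scan oracle including the tie rules
    cand <- curve[d == min(d), ]
    cand <- cand[cand$specificity == max(cand$specificity), ]
    expect_equal(op$sensitivity, max(cand$sensitivity))
  }
  expect_equal(sensitivity_at_spec_closest(curve, 0)$sensitivity, 1)
  expect_equal(sensitivity_at_spec_closest(curve, 0)$specificity, 0)
})

test_that("DeLong placement AUCs equal the trapezoid and degenerate ties give p = 1", {
  set.seed(16)
  n <- 40
  labels <- rep(c("case", "control"), n / 2)
  s1 <- rnorm(n) + (labels == "case")
  s2 <- s1 + rnorm(n, sd = 0.5)
  dl <- delong_test(s1, s2, labels)
  expect_equal(dl$auc_1, auc(empirical_roc(s1, labels)), tolerance = 1e-12)
  expect_equal(dl$auc_2, auc(empirical_roc(s2, labels)), tolerance = 1e-12)
  expect_equal(dl$delta, dl$auc_2 - dl$auc_1)
  expect_gte(dl$variance_delta, 0)

  same <- delong_test(s1, s1, labels)
  expect_equal(same$delta, 0)
  expect_equal(same$p_value, 1)
})

test_that("DeLong agrees with an established reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  labels <- rep(c("case", "control"), each = 30)
  s1 <- rnorm(60) + 0.8 * (labels == "case")
  s2 <- 0.5 * s1 + rnorm(60) + 0.8 * (labels == "case")
  dl <- delong_test(s1, s2, labels)
  ref <- pROC::roc.test(
    pROC::roc(labels, s1, levels = c("control", "case"), direction = "<",
              quiet = TRUE),
    pROC::roc(labels, s2, levels = c("control", "case"), direction = "<",
              quiet = TRUE),
    method = "delong", paired = TRUE)
  expect_equal(dl$p_value, unname(ref$p.value), tolerance = 1e-9)
  expect_equal(dl$auc_1, as.numeric(ref$estimate[1]), tolerance = 1e-12)
  expect_equal(dl$auc_2, as.numeric(ref$estimate[2]), tolerance = 1e-12)
})

test_that("ROC point export writes the three-column CSV", {
  curve <- empirical_roc(c(1, 2, 3, 4), c("control", "control", "case", "case"))
  f <- tempfile(fileext = ".csv")
  write_roc_points(curve, f)
  back <- read.csv(f)
  expect_identical(names(back), c("threshold", "sensitivity", "specificity"))
  expect_equal(nrow(back), nrow(curve))
})
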