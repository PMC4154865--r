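test_that("midrank transform handles ties and sums to n(n+1)/2", {
  expect_error(midrank_transform(numeric(0)), "empty")
  expect_equal(midrank_transform(c(5, 1, 3)), c(3, 1, 2))
  expect_equal(midrank_transform(c(0, 0, 7)), c(1.5, 1.5, 3))
  set.seed(1)
  v <- sample(round(rexp(50, 1e-3)))
  expect_equal(sum(midrank_transform(v)), 50 * 51 / 2)
})

test_that("rank table stores distinct ODs with midranks and round-trips", {
  expect_error(build_rank_table(c(-1, 2)), "negative")
  tab <- build_rank_table(c(0, 0, 10))
  expect_equal(tab$calb_od, c(0, 10))
  expect_equal(tab$rank, c(1.5, 3))
  expect_identical(attr(tab, "n"), 3L)

  expect_equal(build_rank_table(c(4, 2, 9, 1, 7))$rank, 1:5 * 1.0)

  set.seed(2)
  v <- round(rlnorm(40, 7, 1), 1) * rbinom(40, 1, 0.8)
  tab <- build_rank_table(v)
  expect_true(all(diff(tab$calb_od) > 0))
  # lookup of every original value reproduces the midrank transform
  expect_equal(rank_lookup(tab, v, "closest"), midrank_transform(v))
  expect_equal(rank_lookup(tab, v, "linear"), midrank_transform(v))

  f <- tempfile(fileext = ".csv")
  write_rank_table(tab, f)
  back <- read_rank_table(f)
  expect_equal(back$calb_od, tab$calb_od)
  expect_equal(back$rank, tab$rank)
  expect_identical(attr(back, "n"), attr(tab, "n"))
})

test_that("rank lookup interpolates, snaps to the nearest entry and clamps", {
  tab <- build_rank_table(c(100, 200))
  expect_error(rank_lookup(tab, -5), ">= 0")
  expect_equal(rank_lookup(tab, 150, "linear"), 1.5)
  expect_equal(rank_lookup(tab, 190, "closest"), 2)
  expect_equal(rank_lookup(tab, 110, "closest"), 1)
  # equidistant values snap to the upper entry
  expect_equal(rank_lookup(tab, 150, "closest"), 2)
  # clamping outside the observed range
  expect_equal(rank_lookup(tab, 0, "linear"), 1)
  expect_equal(rank_lookup(tab, 1e6, "closest"), 2)

  # a table containing a given OD always returns that entry's stored rank:
  # an OD of 2224 ranked 80th among 326 pooled values stays rank 80
  set.seed(4)
  v <- c(sort(runif(79, 0, 2223)), 2224, runif(246, 2225, 6000))
  tab2 <- build_rank_table(v)
  expect_equal(rank_lookup(tab2, 2224, "closest"), 80)
  expect_equal(rank_lookup(tab2, 2224, "linear"), 80)
})

test_that("null data give a null fit; known coefficients are recovered", {
  # outcome independent of covariates
  set.seed(5)
  rec <- make_records(rep(c("case", "control"), each = 100),
                      rnorm(200, 55, 10), rlnorm(200, 7, 1),
                      rbinom(200, 1, 0.3))
  fit <- fit_logistic(rec, 1)
  expect_true(fit$converged)
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(fit$coefficients["age"]), 3 * se["age"])
  expect_lt(abs(fit$coefficients["fobt"]), 3 * se["fobt"])

  # parameter recovery on n = 2000 drawn from known coefficients
  set.seed(6)
  n <- 2000
  age <- rnorm(n, 58, 11)
  fobt <- rbinom(n, 1, 0.3)
  calb <- rlnorm(n, 7.5, 0.9) * rbinom(n, 1, 0.75)
  rk <- midrank_transform(calb)
  truth <- c(intercept = -6, age = 0.08, fobt = 1.2, rank_calb = 0.002)
  eta <- truth[1] + truth[2] * age + truth[3] * fobt + truth[4] * rk
  y <- rbinom(n, 1, plogis(eta))
  rec <- make_records(ifelse(y == 1, "case", "control"), age, calb, fobt)
  fit2 <- fit_logistic(rec, 2)
  expect_true(fit2$converged)
  se2 <- sqrt(diag(fit2$vcov))
  expect_true(all(abs(fit2$coefficients - truth) < 3 * se2))
})

test_that("tiny-sample log-likelihood matches an independent optimizer", {
  rec <- make_records(rep(c("case", "control"), each = 4),
                      c(61, 48, 55, 66, 52, 63, 58, 45),
                      c(3000, 0, 250, 1200, 0, 2800, 800, 150),
                      c(1, 0, 0, 1, 0, 1, 0, 0))
  fit <- fit_logistic(rec, 2)
  # independent oracle: direct numerical optimization of the likelihood
  X <- cbind(1, rec$age, as.numeric(rec$fobt_positive),
             rank(rec$calb_od))
  y <- as.numeric(rec$group == "case")
  nll <- function(b) -sum(y * (X %*% b) - log1p(exp(X %*% b)))
  opt <- optim(rep(0, 4), nll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  expect_equal(fit$log_lik, -opt$value, tolerance = 1e-6)
})

test_that("separation is reported as non-convergence; Firth stays finite", {
  rec <- make_records(rep(c("case", "control"), each = 5),
                      c(70, 71, 72, 73, 74, 40, 41, 42, 43, 44),
                      c(3000, 0, 1500, 2200, 900, 0, 400, 0, 1100, 250),
                      c(1, 0, 1, 0, 1, 0, 1, 0, 0, 0))
  fit <- fit_logistic(rec, 1)
  expect_false(fit$converged)
  expect_match(attr(fit, "diagnostic"), "separation")
  expect_error(predict_probability(fit, rec), "converge")

  ff <- fit_logistic(rec, 1, firth = TRUE)
  expect_true(ff$converged)
  expect_true(all(is.finite(ff$coefficients)))
  expect_true(all(abs(ff$coefficients) < 20))

  expect_error(fit_logistic(rec[rec$group == "case", ], 1), "control")
})

test_that("predictions invert the logit, respect monotonicity and self-consistency", {
  set.seed(8)
  rec <- signal_cohort(40, 40, effect = 1, seed = 8)
  fit <- fit_logistic(rec, 2)
  p <- predict_probability(fit, rec)
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(stats::sd(p), 0)
  # subjects from the fitting set reproduce in-sample fitted probabilities
  expect_equal(p, fit$fitted, tolerance = 1e-12)

  # increasing CALB never decreases the probability when its slope is > 0
  new <- rec[rep(1, 50), ]
  new$calb_od <- seq(0, 6000, length.out = 50)
  pn <- predict_probability(fit, new)
  if (fit$coefficients["rank_calb"] > 0) expect_true(all(diff(pn) >= 0))

  # all-zero coefficients give probability one half
  fit0 <- fit
  fit0$coefficients[] <- 0
  expect_equal(unique(predict_probability(fit0, rec)), 0.5)
})

test_that("model-2 fit is invariant to monotone transforms and nests model 1", {
  rec <- signal_cohort(35, 30, effect = 1, seed = 9)
  f2 <- fit_logistic(rec, 2)
  rec_t <- rec
  rec_t$calb_od <- log1p(rec$calb_od)^3  # strictly monotone transform
  f2t <- fit_logistic(rec_t, 2)
  expect_equal(f2$log_lik, f2t$log_lik, tolerance = 1e-9)
  expect_equal(predict_probability(f2, rec),
               predict_probability(f2t, rec_t), tolerance = 1e-9)

  f1 <- fit_logistic(rec, 1)
  expect_gte(f2$log_lik, f1$log_lik - 1e-9)
})

test_that("model JSON export carries coefficients and metadata", {
  rec <- signal_cohort(30, 30, seed = 10)
  fit <- fit_logistic(rec, 2)
  f <- tempfile(fileext = ".json")
  write_model(fit, f, rank_table_file = "ranks.csv")
  obj <- jsonlite::read_json(f)
  expect_equal(obj$model, 2)
  expect_equal(unlist(obj$covariates),
               c("intercept", "age", "fobt", "rank_calb"))
  expect_equal(obj$coefficients$age, unname(fit$coefficients["age"]))
  expect_equal(obj$rank_table, "ranks.csv")
})
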