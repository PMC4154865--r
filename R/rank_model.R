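# Rank-transform logistic modelling. CALB optical densities are heavily
# non-normal (zero-inflated, right-skewed), so the model uses their midrank
# 1..n as the covariate; scoring a future subject maps its OD onto the
# fitting set's rank scale through a published-style lookup table.

#' Midrank transform
#'
#' Ranks 1..n with midranks (averages) for ties; the rank sum is always
#' n(n+1)/2.
#'
#' @param values Non-empty numeric vector.
#' @return Numeric vector of midranks.
#' @export
midrank_transform <- function(values) {
  if (!length(values)) stop("empty input", call. = FALSE)
  rank(values, ties.method = "average")
}

#' Build a rank-lookup table
#'
#' One entry per distinct CALB OD with its midrank in the full fitting set —
#' the scoring table published for future subjects. Round-trips exactly
#' through CSV ([write_rank_table()] / [read_rank_table()]).
#'
#' @param calb_values Non-empty numeric vector of ODs (all `>= 0`).
#' @return A `rank_table`: data frame with columns `calb_od` (strictly
#'   increasing) and `rank`, and attribute `n` (number of subjects ranked).
#' @export
build_rank_table <- function(calb_values) {
  if (!length(calb_values)) stop("empty input", call. = FALSE)
  if (any(calb_values < 0)) stop("negative OD values", call. = FALSE)
  r <- midrank_transform(calb_values)
  ord <- order(calb_values)
  keep <- !duplicated(calb_values[ord])
  tab <- data.frame(calb_od = calb_values[ord][keep], rank = r[ord][keep])
  attr(tab, "n") <- length(calb_values)
  class(tab) <- c("rank_table", "data.frame")
  tab
}

#' Look up the rank of a CALB value
#'
#' Exact matches return the stored midrank. Values between two table entries
#' take either the nearest entry's rank (`"closest"`; equidistant values take
#' the upper entry) or the linearly interpolated rank (`"linear"`). Values
#' outside the table's range are clamped to the extreme ranks, keeping the
#' linear predictor finite and the score monotone.
#'
#' @param table A [build_rank_table()] result.
#' @param value Numeric vector of ODs (all `>= 0`).
#' @param method `"closest"` or `"linear"`.
#' @return Numeric vector of ranks.
#' @export
rank_lookup <- function(table, value, method = c("closest", "linear")) {
  method <- match.arg(method)
  if (!inherits(table, "rank_table") || !nrow(table))
    stop("empty or invalid rank table", call. = FALSE)
  if (any(value < 0)) stop("OD values must be >= 0", call. = FALSE)
  x <- table$calb_od; r <- table$rank
  if (nrow(table) == 1L) return(rep(r, length(value)))
  if (method == "linear") {
    stats::approx(x, r, xout = value, method = "linear", rule = 2)$y
  } else {
    # nearest entry; exact ties to the higher OD
    idx <- findInterval(value, x, all.inside = TRUE)
    lo <- x[idx]; hi <- x[idx + 1L]
    nearest <- ifelse(value - lo < hi - value, idx, idx + 1L)
    nearest[value <= x[1L]] <- 1L
    nearest[value >= x[length(x)]] <- length(x)
    r[nearest]
  }
}

#' Write / read a rank-lookup table CSV
#'
#' Two columns `calb_od,rank`, full precision, plus the number of ranked
#' subjects carried in a `# n=` comment line so the table round-trips.
#'
#' @param table A `rank_table`.
#' @param file Path to the CSV file.
#' @return `write_rank_table()`: the path, invisibly; `read_rank_table()`:
#'   the `rank_table`.
#' @export
write_rank_table <- function(table, file) {
  stopifnot(inherits(table, "rank_table"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# n=%d", attr(table, "n")), con)
  writeLines("calb_od,rank", con)
  writeLines(sprintf("%.17g,%.17g", table$calb_od, table$rank), con)
  invisible(file)
}

#' @rdname write_rank_table
#' @export
read_rank_table <- function(file) {
  first <- readLines(file, n = 1L)
  n <- as.integer(sub("^# n=", "", first))
  df <- utils::read.csv(file, comment.char = "#")
  tab <- data.frame(calb_od = df$calb_od, rank = df$rank)
  attr(tab, "n") <- n
  class(tab) <- c("rank_table", "data.frame")
  tab
}

# Negative log-likelihood helpers on the (intercept-first) design matrix.
logistic_loglik <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  sum(y * eta - log1p(exp(eta)))
}

model_design <- function(records, model, rank_table = NULL,
                         lookup = "linear") {
  covars <- c("age", "fobt")
  X <- cbind(intercept = 1, age = records$age,
             fobt = as.numeric(records$fobt_positive))
  if (model == 2L) {
    if (any(is.na(records$calb_od)))
      stop("model 2 requires calb_od on all records", call. = FALSE)
    rk <- if (is.null(rank_table)) midrank_transform(records$calb_od)
          else rank_lookup(rank_table, records$calb_od, lookup)
    X <- cbind(X, rank_calb = rk)
  }
  X
}

# Firth-style Jeffreys-penalized logistic fit (Newton iterations with
# step-halving); used only when requested, e.g. under separation.
fit_firth <- function(X, y, maxit = 100, tol = 1e-8) {
  p <- ncol(X)
  beta <- rep(0, p)
  pen_ll <- function(b) {
    mu <- stats::plogis(drop(X %*% b))
    W <- mu * (1 - mu)
    logistic_loglik(b, X, y) +
      0.5 * determinant(crossprod(X, X * W), logarithm = TRUE)$modulus
  }
  ll <- pen_ll(beta)
  for (it in seq_len(maxit)) {
    mu <- stats::plogis(drop(X %*% beta))
    W <- mu * (1 - mu)
    info <- crossprod(X, X * W)
    info_inv <- tryCatch(solve(info), error = function(e)
      stop("Firth fit failed: singular information ",
           "(collinear or constant covariate)", call. = FALSE))
    h <- rowSums((X %*% info_inv) * X) * W
    score <- drop(crossprod(X, y - mu + h * (0.5 - mu)))
    step <- drop(info_inv %*% score)
    for (half in 0:15) {
      cand <- beta + step / 2^half
      ll_new <- pen_ll(cand)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
    }
    moved <- max(abs(cand - beta))
    beta <- cand; ll <- ll_new
    if (moved < tol) break
  }
  list(beta = beta, vcov = solve(crossprod(X, X * (stats::plogis(drop(X %*% beta)) *
                                                   (1 - stats::plogis(drop(X %*% beta)))))))
}

#' Fit a fecal-marker logistic model
#'
#' Model 1 regresses case status on age and binary FOBT positivity; model 2
#' adds the midrank of the CALB OD computed over the fitting set (and stores
#' the corresponding rank-lookup table for scoring future subjects). Fitting
#' is by maximum likelihood; convergence requires the score vector's max
#' norm to fall below `1e-6`. Complete or quasi-complete separation is
#' reported as non-convergence with a diagnostic; `firth = TRUE` switches to
#' a Jeffreys-penalized fit that remains finite under separation.
#'
#' @param records Subject records with at least one case and one control.
#' @param model `1` (AGE + FOBT) or `2` (AGE + FOBT + rank(CALB)).
#' @param firth Use the penalized fit.
#' @return A `crc_model`: coefficients (log-odds units), `rank_table`
#'   (model 2 only), `log_lik`, `converged`, `vcov`, group counts and the
#'   in-sample `fitted` probabilities.
#' @export
fit_logistic <- function(records, model = c(1L, 2L), firth = FALSE) {
  model <- as.integer(model[1L])
  stopifnot(model %in% 1:2)
  y <- as.numeric(records$group == "case")
  if (!any(y == 1) || !any(y == 0))
    stop("need at least one case and one control", call. = FALSE)
  X <- model_design(records, model)

  separation <- FALSE
  if (firth) {
    ft <- fit_firth(X, y)
    beta <- ft$beta; V <- ft$vcov
    converged <- TRUE
  } else {
    sep_warn <- FALSE
    fit <- withCallingHandlers(
      stats::glm.fit(X, y, family = stats::binomial(),
                     control = stats::glm.control(epsilon = 1e-12,
                                                  maxit = 200)),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      })
    beta <- fit$coefficients
    if (anyNA(beta))
      stop("collinear design: coefficients not estimable (",
           paste(names(beta)[is.na(beta)], collapse = ", "), ")",
           call. = FALSE)
    mu <- fit$fitted.values
    grad <- drop(crossprod(X, y - mu))
    separation <- sep_warn && all(abs(y - mu) < 1e-4)
    converged <- fit$converged && max(abs(grad)) < 1e-6 && !separation
    W <- mu * (1 - mu)
    V <- tryCatch(solve(crossprod(X, X * W)), error = function(e) NULL)
  }
  mu <- stats::plogis(drop(X %*% beta))
  out <- structure(list(
    coefficients = stats::setNames(beta, colnames(X)),
    model = model,
    rank_table = if (model == 2L) build_rank_table(records$calb_od),
    log_lik = logistic_loglik(beta, X, y),
    converged = converged,
    separation = separation,
    firth = firth,
    vcov = V,
    n = length(y), n_case = sum(y), n_control = sum(1 - y),
    fitted = mu
  ), class = "crc_model")
  if (!converged)
    attr(out, "diagnostic") <- if (separation)
      "perfect or quasi-complete separation detected; coefficients diverge (consider firth = TRUE)"
    else "IRLS did not reach the score tolerance"
  out
}

#' @export
print.crc_model <- function(x, ...) {
  cat(sprintf("Fecal-marker logistic model %d (%s)\n", x$model,
              if (x$model == 1L) "AGE + FOBT" else "AGE + FOBT + rank(CALB)"))
  cat(sprintf("  n = %d (%d cases / %d controls), logLik = %.4f, converged: %s\n",
              x$n, x$n_case, x$n_control, x$log_lik, x$converged))
  print(round(x$coefficients, 6))
  if (!x$converged) cat("  note:", attr(x, "diagnostic"), "\n")
  invisible(x)
}

#' Predict the probability of colorectal cancer
#'
#' Inverse-logit of the model's linear predictor. For model 2 the subject's
#' CALB OD is mapped to a rank through the model's stored lookup table
#' ([rank_lookup()]), so scoring uses the fixed fitting-set rank scale; a
#' subject from the fitting set therefore reproduces its in-sample fitted
#' probability exactly.
#'
#' @param model A converged `crc_model`.
#' @param records Subject records with the model's covariates.
#' @param method Rank interpolation for unseen ODs: `"closest"` or
#'   `"linear"`.
#' @return Vector of probabilities in (0, 1).
#' @export
predict_probability <- function(model, records,
                                method = c("linear", "closest")) {
  method <- match.arg(method)
  stopifnot(inherits(model, "crc_model"))
  if (!model$converged)
    stop("model did not converge: ", attr(model, "diagnostic"), call. = FALSE)
  if (any(is.na(records$age)) || any(is.na(records$fobt_positive)))
    stop("missing covariate (age or fobt_positive)", call. = FALSE)
  X <- model_design(records, model$model, rank_table = model$rank_table,
                    lookup = method)
  stats::plogis(drop(X %*% model$coefficients))
}

#' Export a fitted model as JSON
#'
#' Coefficients, covariate names, group sizes and log-likelihood; model 2
#' references its rank table (written separately via [write_rank_table()]).
#'
#' @param model A `crc_model`.
#' @param file Path to the JSON file.
#' @param rank_table_file Optional path recorded as the rank-table reference.
#' @return The path, invisibly.
#' @export
write_model <- function(model, file, rank_table_file = NULL) {
  stopifnot(inherits(model, "crc_model"))
  obj <- list(
    model = model$model,
    covariates = names(model$coefficients),
    coefficients = as.list(model$coefficients),
    n = model$n, n_case = model$n_case, n_control = model$n_control,
    log_lik = model$log_lik, converged = model$converged,
    rank_table = rank_table_file
  )
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(file)
}
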