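# Leave-one-out cross-validation with per-fold operating-point selection:
# each fold refits the model on n-1 subjects (rebuilding the rank table from
# the training fold only), picks the training-probability cutoff whose
# specificity is closest to the target, classifies the held-out subject at
# that cutoff, and records its out-of-fold probability. Bias-corrected
# sensitivity, ROC, AUC and pAUC come from those out-of-fold quantities.

#' Leave-one-out cross-validation of a marker model
#'
#' For each subject in turn: fit the model to the remaining subjects, build
#' the training ROC from their fitted probabilities, select the cutoff at
#' the operating point whose training specificity is closest to
#' `target_spec` (ties to the higher specificity), and classify the held-out
#' subject positive when its predicted probability reaches that cutoff. For
#' model 2 the held-out subject's CALB OD is ranked against the training
#' fold's rank table via [rank_lookup()].
#'
#' @param records Subject records (each fold must retain at least one case
#'   and one control).
#' @param model `1` or `2` (see [fit_logistic()]).
#' @param target_spec Target training specificity for the per-fold cutoff.
#' @param lookup Rank interpolation for the held-out CALB OD (`"linear"` or
#'   `"closest"`).
#' @param pauc_range Specificity range for the cross-validated partial AUC.
#' @param firth Passed to [fit_logistic()].
#' @return A `cv_result` list: `oof_probabilities`, `oof_calls`, `cv_curve`,
#'   `cv_auc`, `cv_pauc`, `cv_sensitivity` (positive-call fraction among
#'   cases), `achieved_specificity` (negative-call fraction among controls),
#'   `target_spec`, `labels`.
#' @export
loocv <- function(records, model = 2L, target_spec = 0.90,
                  lookup = c("linear", "closest"),
                  pauc_range = c(0.90, 1.00), firth = FALSE) {
  lookup <- match.arg(lookup)
  n <- nrow(records)
  y <- records$group == "case"
  if (sum(y) < 2L || sum(!y) < 2L)
    stop("each training fold must retain at least one case and one control",
         call. = FALSE)
  oof_prob <- numeric(n)
  oof_call <- logical(n)
  for (i in seq_len(n)) {
    train <- records[-i, , drop = FALSE]
    fit <- fit_logistic(train, model, firth = firth)
    if (!fit$converged)
      stop(sprintf("fold %d: %s", i, attr(fit, "diagnostic")), call. = FALSE)
    train_prob <- predict_probability(fit, train, method = lookup)
    troc <- empirical_roc(train_prob, train$group)
    cutoff <- sensitivity_at_spec_closest(troc, target_spec)$threshold
    oof_prob[i] <- predict_probability(fit, records[i, , drop = FALSE],
                                       method = lookup)
    oof_call[i] <- oof_prob[i] >= cutoff
  }
  cv_curve <- empirical_roc(oof_prob, records$group)
  structure(list(
    oof_probabilities = oof_prob,
    oof_calls = oof_call,
    cv_curve = cv_curve,
    cv_auc = auc(cv_curve),
    cv_pauc = partial_auc(cv_curve, pauc_range),
    cv_sensitivity = mean(oof_call[y]),
    achieved_specificity = mean(!oof_call[!y]),
    target_spec = target_spec,
    labels = records$group
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("LOOCV: sens %.4f at spec %.4f (target %.2f), AUC %.4f, pAUC %.4f\n",
              x$cv_sensitivity, x$achieved_specificity, x$target_spec,
              x$cv_auc, x$cv_pauc))
  invisible(x)
}

#' Validate a fitted model on an independent cohort
#'
#' Scores the new cohort with the model as fit (model 2 through the model's
#' own stored rank table) and reports the sensitivity at the specificity
#' closest to the target, the achieved specificity, AUC and partial AUC.
#'
#' @param model A converged `crc_model`.
#' @param records The validation cohort.
#' @param target_spec Target specificity for the reported operating point.
#' @param lookup Rank interpolation for unseen CALB ODs.
#' @param pauc_range Specificity range for the partial AUC.
#' @return List with `sensitivity`, `specificity`, `threshold`, `auc`,
#'   `pauc`, `curve` and the score vector `probabilities`.
#' @export
external_validate <- function(model, records, target_spec = 0.90,
                              lookup = c("linear", "closest"),
                              pauc_range = c(0.90, 1.00)) {
  lookup <- match.arg(lookup)
  prob <- predict_probability(model, records, method = lookup)
  curve <- empirical_roc(prob, records$group)
  op <- sensitivity_at_spec_closest(curve, target_spec)
  list(sensitivity = op$sensitivity, specificity = op$specificity,
       threshold = op$threshold, auc = auc(curve),
       pauc = partial_auc(curve, pauc_range), curve = curve,
       probabilities = prob)
}

#' Fit the final model on the pooled development and validation sets
#'
#' The final model for future subjects is refit on the union of both
#' cohorts; for model 2 this exports the pooled rank-lookup table that
#' future CALB ODs are scored against.
#'
#' @param dev,val Subject-record data frames for the two cohorts.
#' @param model `1` or `2`.
#' @param firth Passed to [fit_logistic()].
#' @return A `crc_model` fit to the pooled records.
#' @export
fit_total <- function(dev, val, model = 2L, firth = FALSE) {
  if (missing(val) || is.null(val) || !nrow(val) || !nrow(dev))
    stop("both cohorts must be present", call. = FALSE)
  fit_logistic(rbind(dev, val), model, firth = firth)
}
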