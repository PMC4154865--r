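# End-to-end study workflow: fit both nested models on the development set,
# bias-correct by LOOCV, validate externally, refit on the pooled total set,
# and compare the models by DeLong AUC increase and reclassification, all
# collected into a machine-readable report.

#' Binarize a continuous FOBT measurement
#'
#' Positive at or above the analytical cutoff (default 100 ng Hb/ml); the
#' boundary value itself is positive.
#'
#' @param fobt_ng_ml Numeric vector of ng Hb/ml values (all `>= 0`).
#' @param cutoff Positivity cutoff in ng Hb/ml.
#' @return Logical vector.
#' @export
fobt_binarize <- function(fobt_ng_ml, cutoff = 100) {
  if (any(fobt_ng_ml < 0, na.rm = TRUE))
    stop("FOBT values must be >= 0", call. = FALSE)
  fobt_ng_ml >= cutoff
}

#' Study configuration
#'
#' Settings shared across the pipeline stages.
#'
#' @param target_spec Target specificity for operating points and per-fold
#'   LOOCV cutoffs.
#' @param pauc_range Specificity range of the partial AUC.
#' @param fobt_cutoff FOBT positivity cutoff (ng Hb/ml).
#' @param lookup Rank interpolation for scoring unseen CALB ODs.
#' @param comparison_datasets Datasets on which the model-1 vs model-2
#'   comparisons (DeLong, reclassification) are run.
#' @param seed Optional integer echoed into the report for provenance.
#' @return A `study_config` list.
#' @export
study_config <- function(target_spec = 0.90, pauc_range = c(0.90, 1.00),
                         fobt_cutoff = 100,
                         lookup = c("linear", "closest"),
                         comparison_datasets = c("development", "validation",
                                                 "total"),
                         seed = NULL) {
  lookup <- match.arg(lookup)
  comparison_datasets <- match.arg(comparison_datasets, several.ok = TRUE)
  structure(list(target_spec = target_spec, pauc_range = pauc_range,
                 fobt_cutoff = fobt_cutoff, lookup = lookup,
                 comparison_datasets = comparison_datasets, seed = seed,
                 schema_version = "1.0"),
            class = "study_config")
}

# AUC with a 95% Wald CI from placement-value (structural-component)
# variance — the single-model arm of the DeLong machinery.
auc_with_ci <- function(scores, labels) {
  y <- as_case_logical(labels)
  pv <- placement_values(scores, y)
  a <- mean(pv$v10)
  v <- stats::var(pv$v10) / sum(y) + stats::var(pv$v01) / sum(!y)
  list(auc = a, ci = a + c(-1, 1) * stats::qnorm(0.975) * sqrt(max(v, 0)))
}

metric_block <- function(scores, labels, config) {
  curve <- empirical_roc(scores, labels)
  op <- sensitivity_at_spec_closest(curve, config$target_spec)
  ac <- auc_with_ci(scores, labels)
  list(sensitivity = op$sensitivity,
       specificity = op$specificity,
       threshold = op$threshold,
       auc = ac$auc, auc_ci_95 = ac$ci,
       pauc = partial_auc(curve, config$pauc_range))
}

#' Run the full development / validation / total-set study
#'
#' Executes the complete workflow for both nested models (model 1:
#' AGE + FOBT; model 2: AGE + FOBT + rank(CALB)): apparent fit and metrics
#' on the development set, leave-one-out bias correction with per-fold
#' cutoff selection, external validation on the independent cohort, refit
#' on the pooled total set, and model comparisons (DeLong AUC increase,
#' category-free reclassification/NRI) on each configured dataset. For the
#' validation dataset the comparison scores are the development-set models'
#' predictions; for development and total they are the apparent fitted
#' probabilities of models fit to that set.
#'
#' @param dev,val Subject-record data frames or paths to cohort CSVs.
#' @param config A [study_config()].
#' @return A `study_report` list with blocks `development_apparent`,
#'   `development_loocv`, `validation`, `total` (each holding model-1 and
#'   model-2 metrics), `comparisons`, `final_model` (pooled model-2
#'   coefficients), `descriptives` and a `config` echo.
#' @export
run_study <- function(dev, val, config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  if (is.character(dev)) dev <- read_cohort(dev)
  if (is.character(val)) val <- read_cohort(val)
  validate_records(dev, config$fobt_cutoff)
  validate_records(val, config$fobt_cutoff)
  total <- rbind(dev, val)

  fits_dev <- lapply(1:2, function(m) fit_logistic(dev, m))
  fits_total <- lapply(1:2, function(m) fit_logistic(total, m))
  for (f in c(fits_dev, fits_total))
    if (!f$converged)
      stop("model ", f$model, " fit did not converge: ",
           attr(f, "diagnostic"), call. = FALSE)

  scores <- list(
    development = lapply(fits_dev, function(f)
      predict_probability(f, dev, method = config$lookup)),
    validation = lapply(fits_dev, function(f)
      predict_probability(f, val, method = config$lookup)),
    total = lapply(fits_total, function(f)
      predict_probability(f, total, method = config$lookup))
  )
  labels <- list(development = dev$group, validation = val$group,
                 total = total$group)

  block_for <- function(dataset) {
    stats::setNames(lapply(1:2, function(m)
      metric_block(scores[[dataset]][[m]], labels[[dataset]], config)),
      c("model_1", "model_2"))
  }

  cv <- lapply(1:2, function(m)
    loocv(dev, m, target_spec = config$target_spec, lookup = config$lookup,
          pauc_range = config$pauc_range))
  loocv_block <- stats::setNames(lapply(cv, function(r)
    list(sensitivity = r$cv_sensitivity,
         specificity = r$achieved_specificity,
         auc = auc_with_ci(r$oof_probabilities, r$labels)$auc,
         auc_ci_95 = auc_with_ci(r$oof_probabilities, r$labels)$ci,
         pauc = r$cv_pauc)), c("model_1", "model_2"))

  comparisons <- lapply(config$comparison_datasets, function(ds) {
    dl <- delong_test(scores[[ds]][[1]], scores[[ds]][[2]], labels[[ds]])
    rc <- reclassification(scores[[ds]][[1]], scores[[ds]][[2]],
                           labels[[ds]])
    list(dataset = ds, delong = unclass(dl), reclassification = unclass(rc))
  })
  names(comparisons) <- config$comparison_datasets

  report <- structure(list(
    schema_version = config$schema_version,
    config = unclass(config),
    n = list(development = nrow(dev), validation = nrow(val),
             total = nrow(total)),
    descriptives = list(development = descriptive_table(dev),
                        validation = descriptive_table(val)),
    development_apparent = block_for("development"),
    development_loocv = loocv_block,
    validation = block_for("validation"),
    total = block_for("total"),
    comparisons = comparisons,
    final_model = list(
      coefficients = as.list(fits_total[[2]]$coefficients),
      log_lik = fits_total[[2]]$log_lik,
      n = fits_total[[2]]$n)
  ), class = "study_report")
  attr(report, "models") <- list(development = fits_dev, total = fits_total)
  report
}

#' @export
print.study_report <- function(x, ...) {
  fmt <- function(b) sprintf("sens %6.2f%% at spec %6.2f%%, AUC %6.2f%%, pAUC %5.2f%%",
                             100 * b$sensitivity, 100 * b$specificity,
                             100 * b$auc, 100 * b$pauc)
  cat("Study report (development n =", x$n$development,
      ", validation n =", x$n$validation, ")\n")
  for (blk in c("development_apparent", "development_loocv", "validation",
                "total")) {
    cat(" ", blk, "\n")
    cat("    model 1:", fmt(x[[blk]]$model_1), "\n")
    cat("    model 2:", fmt(x[[blk]]$model_2), "\n")
  }
  for (cmp in x$comparisons)
    cat(sprintf("  %s: dAUC = %+.4f (DeLong p = %s), NRI = %+.4f (p = %s)\n",
                cmp$dataset, cmp$delong$delta,
                format.pval(cmp$delong$p_value, digits = 4),
                cmp$reclassification$nri,
                format.pval(cmp$reclassification$p_nri, digits = 4)))
  invisible(x)
}

#' Write a study report as JSON
#'
#' Full-precision probabilities, versioned schema; reproduces byte-for-byte
#' under identical inputs and configuration.
#'
#' @param report A [run_study()] result.
#' @param file Path to the JSON file.
#' @return The path, invisibly.
#' @export
write_study_report <- function(report, file) {
  stopifnot(inherits(report, "study_report"))
  jsonlite::write_json(unclass(report), file, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(file)
}

#' Descriptive cohort summary with group tests
#'
#' Regenerates the descriptive table for a cohort: CALB medians and ranges
#' with the case/control Wilcoxon rank-sum p-value and the across-stage
#' Kruskal-Wallis p-value, and FOBT positivity by group, stage and site with
#' Pearson chi-square p-values.
#'
#' @param records Subject records for one cohort.
#' @return Nested list of summaries.
#' @export
descriptive_table <- function(records) {
  validate_records(records)
  y <- records$group == "case"
  calb_sum <- function(v) list(n = length(v), median = stats::median(v),
                               range = range(v))
  fobt_sum <- function(f) list(positive = sum(f), n = length(f),
                               rate = mean(f))
  cases <- records[y, , drop = FALSE]
  ctrls <- records[!y, , drop = FALSE]
  stages <- intersect(T_STAGES, unique(cases$t_stage))
  by_stage <- lapply(stages, function(s) {
    sub <- cases[cases$t_stage == s, , drop = FALSE]
    list(calb = calb_sum(sub$calb_od), fobt = fobt_sum(sub$fobt_positive))
  })
  names(by_stage) <- stages
  sites <- intersect(c("right", "left"), unique(cases$site))
  by_site <- lapply(sites, function(s) {
    sub <- cases[cases$site == s, , drop = FALSE]
    list(calb = calb_sum(sub$calb_od), fobt = fobt_sum(sub$fobt_positive))
  })
  names(by_site) <- sites

  stage_groups <- lapply(stages, function(s)
    cases$calb_od[cases$t_stage == s])
  fobt_tab <- rbind(c(sum(cases$fobt_positive),
                      sum(!cases$fobt_positive)),
                    c(sum(ctrls$fobt_positive),
                      sum(!ctrls$fobt_positive)))
  fobt_stage_tab <- do.call(rbind, lapply(stages, function(s) {
    f <- cases$fobt_positive[cases$t_stage == s]
    c(sum(f), sum(!f))
  }))

  safe_p <- function(expr) tryCatch(expr$p_value, error = function(e) NA_real_)
  list(
    cases = list(calb = calb_sum(cases$calb_od),
                 fobt = fobt_sum(cases$fobt_positive),
                 by_stage = by_stage, by_site = by_site),
    controls = list(calb = calb_sum(ctrls$calb_od),
                    fobt = fobt_sum(ctrls$fobt_positive)),
    tests = list(
      calb_case_vs_control_p = safe_p(
        wilcoxon_rank_sum(cases$calb_od, ctrls$calb_od)),
      calb_by_stage_p = if (length(stage_groups) >= 2)
        safe_p(kruskal_wallis(stage_groups)) else NA_real_,
      fobt_case_vs_control_p = safe_p(pearson_chi_square(fobt_tab)),
      fobt_by_stage_p = if (nrow(fobt_stage_tab) >= 2)
        safe_p(pearson_chi_square(fobt_stage_tab)) else NA_real_
    )
  )
}
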