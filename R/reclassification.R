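# Category-free reclassification improvement. Comparing a newer model's
# predicted probabilities with an older model's on the same subjects: RI in
# cases is the fraction moving up minus the fraction moving down, RI in
# controls the fraction moving down minus up, and their sum is the net
# reclassification improvement (NRI), each with an asymptotic z-test.

#' Reclassification improvement and NRI
#'
#' Computes, separately in cases and controls, the proportions of subjects
#' whose predicted probability is strictly higher or strictly lower under
#' the new model (exact ties count in neither direction), the resulting
#' reclassification improvements, and the category-free NRI with asymptotic
#' two-sided z-tests. The per-group variance is
#' `(p_up + p_down - (p_up - p_down)^2) / n`; the NRI variance is the sum of
#' the two group variances.
#'
#' @param p_old,p_new Predicted probabilities from the older and newer model
#'   on the same subjects, in \[0, 1\].
#' @param labels Case/control labels (see [empirical_roc()]).
#' @return A `reclass_result` list: `p_up_case`, `p_down_case`,
#'   `p_up_ctrl`, `p_down_ctrl`, `ri_case`, `ri_ctrl`, `nri`, `z_case`,
#'   `z_ctrl`, `z_nri`, `p_case`, `p_ctrl`, `p_nri`, `n_case`, `n_control`.
#' @export
reclassification <- function(p_old, p_new, labels) {
  y <- as_case_logical(labels)
  if (length(p_old) != length(p_new) || length(p_old) != length(y))
    stop("length mismatch", call. = FALSE)
  if (any(p_old < 0 | p_old > 1 | p_new < 0 | p_new > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (!any(y) || all(y)) stop("empty group", call. = FALSE)
  up <- p_new > p_old
  down <- p_new < p_old

  grp <- function(sel) {
    n <- sum(sel)
    pu <- mean(up[sel]); pd <- mean(down[sel])
    v <- (pu + pd - (pu - pd)^2) / n
    list(pu = pu, pd = pd, n = n, v = v)
  }
  cs <- grp(y); ct <- grp(!y)
  ri_case <- cs$pu - cs$pd
  ri_ctrl <- ct$pd - ct$pu
  nri <- ri_case + ri_ctrl
  ztest <- function(est, v) {
    if (v <= 0) {
      z <- if (est == 0) 0 else NA_real_
      p <- if (est == 0) 1 else NA_real_
    } else {
      z <- est / sqrt(v)
      p <- 2 * stats::pnorm(-abs(z))
    }
    c(z = z, p = p)
  }
  tc <- ztest(ri_case, cs$v)
  tt <- ztest(ri_ctrl, ct$v)
  tn <- ztest(nri, cs$v + ct$v)
  structure(list(
    p_up_case = cs$pu, p_down_case = cs$pd,
    p_up_ctrl = ct$pu, p_down_ctrl = ct$pd,
    ri_case = ri_case, ri_ctrl = ri_ctrl, nri = nri,
    z_case = tc[["z"]], z_ctrl = tt[["z"]], z_nri = tn[["z"]],
    p_case = tc[["p"]], p_ctrl = tt[["p"]], p_nri = tn[["p"]],
    n_case = cs$n, n_control = ct$n
  ), class = "reclass_result")
}

#' @export
print.reclass_result <- function(x, ...) {
  cat(sprintf("Reclassification improvement (category-free)\n  RI cases    = %+.4f (p = %s)\n  RI controls = %+.4f (p = %s)\n  NRI         = %+.4f (p = %s)\n",
              x$ri_case, format.pval(x$p_case, digits = 4),
              x$ri_ctrl, format.pval(x$p_ctrl, digits = 4),
              x$nri, format.pval(x$p_nri, digits = 4)))
  invisible(x)
}
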