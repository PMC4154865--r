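# Fixtures built in code: hand-sized subject-record frames and a quick
# cohort sampler with explicit signal control.

make_records <- function(group, age, calb, fobt,
                         cohort = "development") {
  n <- length(group)
  data.frame(
    id = sprintf("s%03d", seq_len(n)),
    cohort = cohort,
    group = group,
    age = age,
    calb_od = calb,
    fobt_ng_ml = NA_real_,
    fobt_positive = as.logical(fobt),
    t_stage = ifelse(group == "case", "T3", "none"),
    site = ifelse(group == "case", "left", "none"),
    stringsAsFactors = FALSE
  )
}

# Cohort drawn from an explicit case-control process; `effect` scales the
# case-control separation of every covariate (0 = labels pure noise).
signal_cohort <- function(n_case, n_control, effect = 1, seed = 1) {
  set.seed(seed)
  n <- n_case + n_control
  group <- rep(c("case", "control"), c(n_case, n_control))
  is_case <- group == "case"
  age <- rnorm(n, 56 + ifelse(is_case, 7, -6) * effect, 10.5)
  p_zero <- ifelse(is_case, 0.6 - 0.4 * min(effect, 1), 0.6)
  med <- ifelse(is_case, 500 + 2500 * effect, 500)
  calb <- ifelse(runif(n) < p_zero, 0, rlnorm(n, log(med), 0.7))
  fobt <- runif(n) < ifelse(is_case, 0.05 + 0.45 * min(effect, 2), 0.02)
  make_records(group, pmax(age, 18.5), calb, fobt)
}
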