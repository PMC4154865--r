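---
title: "Combining FOBT and fecal calgranulin B in a rank-based prediction model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combining FOBT and fecal calgranulin B in a rank-based prediction model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcmarkers)
```

## The problem

Fecal screening for colorectal cancer (CRC) leans on the immunochemical
fecal occult blood test (FOBT), which has good specificity but only
moderate sensitivity, especially for early (T1) tumours that bleed
intermittently. Fecal calgranulin B (CALB, S100A9; a calprotectin
subunit) is shed by tumour and inflamed mucosa regardless of bleeding,
so its western-blot optical density (OD) carries complementary signal.
`crcmarkers` implements the full statistical machinery for combining the
two markers into an age-adjusted logistic prediction model, validating
it, and quantifying the incremental value of CALB.

## The model

Two nested logistic regressions are compared on case-control data:

* **Model 1**: `logit P(CRC) = b0 + b1*AGE + b2*FOBT`
* **Model 2**: `logit P(CRC) = b0 + b1*AGE + b2*FOBT + b3*R(CALB)`

with FOBT the binary positivity indicator (positive at >= 100 ng Hb/ml,
boundary inclusive) and `R(CALB)` the *midrank* of the subject's CALB OD
among the fitting set's n values (ties receive average ranks, so the
ranks always sum to n(n+1)/2). Ranks are used because stool ODs are
grossly non-normal — zero-inflated and right-skewed — and the rank
covariate makes the fit invariant to any strictly monotone
transformation of the raw ODs (a property the test suite asserts
exactly). Raw ranks 1..n are used rather than ranks rescaled to [0, 1];
that keeps the published-style lookup table directly interpretable.

A fitted model 2 carries its **rank table**: one row per distinct OD
with its midrank. A future subject's OD is scored through
`rank_lookup()`: exact matches return the stored midrank; values between
two entries take either the nearest entry's rank (`closest`) or a
linearly interpolated rank (`linear`, the default — it is continuous and
strictly monotone between entries, which `closest` is not); values
outside the observed range are clamped to the extreme ranks so the
linear predictor stays finite. Equidistant `closest` queries snap to the
higher OD.

Age enters linearly (nothing in the design motivates more structure) and
is included in both models because cases run substantially older than
controls in both cohorts; omitting it would credit the markers with an
age effect.

## Study workflow

`run_study()` reproduces the standard development/validation workflow:

1. fit both models to the development cohort (apparent metrics);
2. bias-correct internally by leave-one-out cross-validation;
3. validate externally on the independent cohort, scoring through the
   development model's own rank table;
4. refit on the pooled total set — the final model for future subjects,
   whose pooled rank table is the published scoring input;
5. compare the models by the DeLong paired AUC test and by
   category-free reclassification (RI/NRI).

Performance is read off the empirical ROC curve (positive call at
score >= threshold): the sensitivity at the operating point whose
specificity is *closest* to 90% (reported with the achieved
specificity), the trapezoidal AUC (identical to the Mann-Whitney
probability with ties counted one half), and the partial AUC over
specificity 90-100%, reported unnormalized so its maximum is the band
width 0.10. When two operating points sit equidistant from the target
specificity the higher specificity wins — the conservative choice for a
screening context. McClish standardization of the pAUC is available but
off by default.

**LOOCV with per-fold cutoffs.** Each fold refits the model on n-1
subjects — for model 2 the rank table is rebuilt from the training fold
only, and the held-out OD is ranked against it by interpolation — then
selects the probability cutoff at the training operating point closest
to 90% specificity and classifies the held-out subject at that cutoff.
Cross-validated sensitivity/specificity come from the pooled out-of-fold
calls, and the cross-validated ROC/AUC/pAUC from the pooled out-of-fold
probabilities. How the left-out CALB value should be ranked is not
dictated by the workflow itself; linear interpolation is the default and
`closest` is available (the choice is configurable precisely because it
is the one genuinely open decision in the procedure).

A known artifact of pooling out-of-fold probabilities deserves note:
leaving out a case lowers the training prevalence, so cases receive
systematically slightly lower out-of-fold probabilities than controls.
With real signal this is the (desired) optimism correction; under a pure
null, where fitted slopes are near zero, the label-linked shift can
dominate the negligible covariate spread and push the cross-validated
AUC far *below* 0.5. The test suite therefore checks the null case
one-sidedly (no manufactured discrimination) and checks the optimism
direction on signal-bearing cohorts.

## Model comparison

The DeLong test estimates the covariance of the two correlated AUCs from
placement values (each case's fraction of controls beaten, ties one
half, and vice versa), giving a normal z-test for the AUC increase and
Wald 95% CIs per AUC. Degenerate variance (identical placements) is
reported as p = 1 when the difference is exactly zero and NA otherwise.

Category-free reclassification improvement counts, per group, subjects
whose predicted probability strictly rises or strictly falls under
model 2; exact ties count in neither direction, matching the strict
inequality in the definition. RI(cases) = up - down, RI(controls) =
down - up, NRI = RI(cases) + RI(controls) in [-2, 2], each with the
asymptotic variance `(p_up + p_down - (p_up - p_down)^2)/n` (summed for
the NRI) and a two-sided z-test. This asymptotic test is known to be
anti-conservative; the suite's calibration check uses a deliberately
loose [2%, 10%] type-I band at nominal 5%. Unlike the AUC, the NRI is
*not* invariant under recalibration of one model's probabilities — a
documented behaviour, not a defect.

## Design calculations

`exact_lower_limit()` inverts the binomial tail (Clopper-Pearson) via
the beta quantile; `assurance_probability()` enumerates k = 0..n exactly
to give the probability that the observed limit clears a floor; and
`required_n()` scans n upward, reporting honestly (via the `stable`
attribute) when the exact-binomial saw-tooth makes the assurance dip
back below target just above the solution. One-sided limits are the
default: the design statements this module reproduces concern a "95%
lower confidence limit", and the one-sided computation reproduces the
published 99 / 85 / 99.5 / 87.3 assurance quadruple to within a printed
point, while a two-sided limit misses it by tens of points. The
saw-tooth observed on the n = 50..150 grid at (true 0.90, floor 0.75)
reaches 0.0121 per step, which is why the monotonicity test allows
drops up to 0.015.

## The synthetic cohort generator

No subject-level data accompany the study this package operationalizes,
so `generate_cohort()` draws cohorts with the published summary
structure; every downstream stage is exercised against it.

* **Counts, stages, sites, ages** follow the published tables: 81/51
  (development) and 94/100 (validation); stage mixtures (14, 10, 47,
  10)/81 and (10, 8, 59, 17)/94; site mixtures 21/60 and 25/69; ages
  normal with the printed means/SDs (63.16/10.42, 50.24/10.12,
  62.96/11.97, 49.43/10.78), truncated at 18 years.
* **FOBT** is drawn binary per stage at the printed stage-wise
  positivity rates (7.1%, 60%, 55.3%, 90% in development; 20%, 25%,
  62.7%, 64.7% in validation) and 1/51 resp. 0/100 in controls, so the
  stage-weighted case positivity reproduces the printed 51.9% / 55.3%.
  An optional continuous mode draws ng/ml values as truncated
  exponentials below and shifted exponentials above the 100 ng/ml
  cutoff, consistent with the positivity call, for cutoff-logic tests.
* **CALB OD** is zero-inflated: a point mass at 0 plus a log-normal
  positive part truncated to the published range. The truncated
  location is solved numerically so the *truncated* median equals the
  configured one. Published values fix the control median at 0 (hence
  zero-inflation >= 0.5; 0.60 chosen) and the case overall medians
  (2557.5 / 2968.6); the case zero fraction (0.20) reflects the zeros
  visible in nearly every published stage range together with the
  reported ~72% standalone sensitivity of CALB, and the positive-part
  medians (3050 / 3450) are set so the implied overall medians land on
  the published ones. The control positive-part median (500 / 450,
  log-scale SD 1.0) encodes occasional false-positive shedding
  (functional bowel disease) reaching the published control maxima;
  case log-scale SD 0.55 keeps the positive part inside the published
  ranges with realistic spread.
* **Dependence**: CALB and FOBT are conditionally independent given
  group and stage. Nothing published constrains their within-subject
  dependence; this is a modelling assumption of the generator, not a
  claim about the biology, and it is the main respect in which passing
  tests do not certify behaviour on real data (a positive CALB-FOBT
  correlation within cases would shrink the incremental value of CALB).
* A single seeded RNG stream governs all draws, so a configuration
  reproduces its cohort exactly; the global RNG state is restored on
  exit.

Simulated cohorts at these defaults separate cases from controls
somewhat more cleanly than the original cohorts did (synthetic AUCs run
a few points above the published ones) — unsurprising, since the
generator draws from smooth parametric families calibrated only to
medians, ranges and rates. All package-level guarantees are therefore
directional or self-consistent rather than anchored to the published
AUCs.

## Numerical choices

* Logistic fits use iteratively reweighted least squares with a
  tightened convergence tolerance (`epsilon = 1e-12`, 200 iterations);
  a fit is declared converged only if the score vector's max norm is
  below 1e-6. Complete/quasi-complete separation is detected (saturated
  fitted probabilities matching the outcome) and reported as
  non-convergence with a diagnostic rather than silently returning
  divergent coefficients; collinear designs error out by name.
* A Firth-style Jeffreys-penalized fit (`firth = TRUE`) — Newton
  iterations on the penalized score with step-halving — is provided for
  separated data and used off by default, since plain maximum
  likelihood is the reference procedure.
* Probabilities are compared and serialized at full precision; reports
  are byte-identical under identical inputs and configuration.

## Problem sizes in the test suite

The suite verifies large-sample recovery at 5,000-10,000 subjects per
group, oracle equivalences on 16-60-subject samples (O(n^2) pairwise AUC,
permutation and closed-form test oracles, an independent numerical
optimizer at n = 8), calibration bands over 500-1,000 simulation
replicates, and the LOOCV optimism direction over 100 cohorts at the
published 81/51 sizes. These sizes were chosen so each statistical check
has enough resolution for its stated tolerance while the whole suite
stays quick enough to run routinely.

## Limitations

* The generator emulates marginal summaries, not subject-level reality:
  no densitometry noise or batch effects, no symptom covariates, and
  conditional independence of the markers as noted above.
* The final published equation's numeric coefficients are not
  transcribed anywhere recoverable, so the package reports its own
  coefficients; agreement with the original fit cannot be checked.
* Only LOOCV is implemented (as published) — no k-fold or bootstrap
  validation; no categorical NRI and no IDI; no smoothed/binormal ROC
  models or confidence bands on the whole curve.
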