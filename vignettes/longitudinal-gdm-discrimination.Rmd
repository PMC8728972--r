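---
title: "Longitudinal discriminant analysis of early-pregnancy biomarker panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal discriminant analysis of early-pregnancy biomarker panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Gestational diabetes mellitus (GDM) is diagnosed at 24–28 weeks of
gestation by a two-step glucose protocol (50-g glucose load screen, then a
100-g OGTT judged by the Carpenter–Coustan criteria; both rules are
implemented in `carpenter_coustan()` and `two_step_diagnose()` with
inclusive thresholds). The screening question this package addresses is
whether four routine complete-blood-count quantities — hemoglobin (Hb),
hematocrit (Hct), fasting blood sugar (FBS) and red blood cell count
(RBC) — measured twice, in the first trimester and in weeks 16–20, can
classify women as future GDM/non-GDM months earlier.

The statistical idea is longitudinal discriminant analysis built on a
multivariate linear mixed model: model all four biomarker trajectories
jointly, then allocate each woman with the Gaussian likelihood-ratio rule
that the fitted model implies.

## The model

For subject $i$, stack the four biomarkers at the two visits (visits
nested within biomarker) into $y_i \in \mathbb{R}^8$ and write

$$y_i = X_i\beta + Z_i b_i + \varepsilon_i, \qquad
  b_i \sim N(0, D), \qquad \varepsilon_i \sim N(0, \Omega_i).$$

Concrete choices, all visible in `model_spec()` and `mlmm_fit()`:

* **Mean structure.** Every covariate receives a biomarker-specific
  coefficient (a seemingly-unrelated-regressions layout). Each biomarker
  block holds an intercept, the GDM indicator (0/1), the visit indicator
  (0/1), and maternal age (years), BMI (kg/m²), SBP and DBP (mmHg; both
  visit-specific). Biomarkers live on incommensurable scales (g/dL vs
  mg/dL), so shared coefficients across biomarkers would be meaningless.
  A group × time interaction is available behind a flag but off by
  default: with two visits it is weakly informed, and the motivating
  analysis found no significant interactions.
* **Random structure.** One random intercept per biomarker with
  unstructured $4\times4$ $D$ — the richest subject-level structure
  identifiable with $t = 2$ visits; random slopes are not identifiable
  here and are deliberately absent.
* **Error structure.** Diagonal, with biomarker-specific variances;
  cross-biomarker and cross-visit dependence is carried entirely by $D$.
  A separable (Kronecker) error structure was considered and rejected:
  with $t = 2$ and an unstructured $D$ already absorbing between-marker
  covariance, its extra correlation parameters are weakly identified.
* **Estimation.** Direct maximum likelihood (not REML — the discriminant
  uses the ML objective). The covariance parameters are optimized by BFGS
  on an unconstrained scale (log-Cholesky factor of $D$, log variances);
  $\beta$ is profiled out by GLS at every step. Because the design is
  balanced, $V = Z D Z' + \Omega$ is shared across subjects, and the
  likelihood is evaluated from pre-computed cross-product statistics, so
  one evaluation costs $O(q^2 k^2)$ regardless of $n$. Starting values
  are method-of-moments estimates from OLS residuals; convergence is the
  optimizer's relative-tolerance criterion ($10^{-10}$) with a
  Nelder–Mead polish and an explicit `converged` flag on failure.
  A rank-deficient fixed-effects design is refused with the collinear
  columns named; a non-positive-definite $V$ during search is rejected by
  penalty rather than crashing.

## The allocation rule

With fitted $\hat\beta, \hat D, \hat\Omega$ and
$V_i = Z_i \hat D Z_i' + \hat\Omega_i$, define for each woman the two
conditional means $\mu_{1i}, \mu_{2i}$ (her design with the group
indicator forced to non-GDM/GDM, everything else at observed values) and
the score

$$L_i = (\mu_{1i}-\mu_{2i})' V_i^{-1}
        \bigl(y_i - \tfrac12(\mu_{1i}+\mu_{2i})\bigr),$$

allocating to non-GDM iff $L_i \ge \ln(\pi_2/\pi_1)$, ties to non-GDM.
This is the equal-covariance Gaussian Bayes classifier in disguise;
`posterior()` exposes the probabilistic form
$p_1 = \mathrm{logit}^{-1}(L_i - \ln(\pi_2/\pi_1))$, computed in log
space so scores of several hundred stay finite. Priors default to the
sample group proportions (the published cohort's 49/600), overridable.

The univariate strategy is the identical machinery with a single-marker
`model_spec()` ($q = 2$); the multivariate strategy uses all four
($q = 8$).

Performance is reported two ways, clearly labelled: resubstitution
(each woman scored by the model fitted on the full sample — presumed to
match the original analysis, which does not describe a validation
scheme) and stratified k-fold cross-validation (default $k = 10$, priors
re-estimated per training split). Resubstitution is structurally
optimistic: under a pure null its AUC sits above 0.5 because the group
contrast is estimated from the scored subjects themselves. All
calibration claims in the test suite are therefore made on out-of-fold
scores.

## ROC evaluation

The ROC positive class is GDM and the risk marker is the *negated*
discriminant score (the score is oriented toward non-GDM); this
orientation is fixed in one place (`risk_from_scores()`) to prevent
silent $1-\mathrm{AUC}$ errors. `auc_mann_whitney()` is the tie-aware
rank estimator and equals the trapezoidal area under `roc_curve()`
exactly. Confidence intervals: DeLong structural components by default,
stratified bootstrap percentile (2000 resamples, seeded) as an option —
the original report does not state its CI method. Two named operating
points are reported, since the published sensitivity/specificity pair
does not state its threshold: "bayes" ($\ln(\pi_2/\pi_1)$) and "youden"
(maximizing $J$, ties to the lower threshold). Integer percentages
appear only in the rendered Markdown report (round-half-up); JSON keeps
full precision.

## The synthetic cohort

The patient-level data behind the motivating study are not deposited, so
`default_cohort_params()` encodes what *is* published, and
`generate_cohort()` simulates from it:

* n = 600, GDM prevalence 8.2% (label drawn first, Bernoulli);
* per (biomarker, group, visit) means and SDs exactly as published. One
  printed value — the RBC SD of 5.01 for non-GDM visit 1, against a mean
  of 4.39 ×10¹²/L — is physiologically impossible (it would imply ~19%
  negative red-cell counts) and is corrected to 0.51;
* covariate distributions (age, visit-specific BMI/SBP/DBP, parity,
  education) per the published group summaries.

What is **not** published, and therefore an explicit assumption of the
generator (configurable, and honestly the quantity the multivariate AUC
is most sensitive to): the correlation structure. Defaults are 0.65
between Hb and Hct, 0.45 between RBC and each of Hb/Hct, 0.10 between
FBS and the hematologic markers — physiologically plausible values for
hemoconcentration-linked indices — with 0.5 between the two visits of
the same biomarker and 0.7 for the visit-specific covariates. The
implied 8×8 covariance is the Kronecker product of the marker and visit
correlations, scaled by group/visit SDs, and is checked positive
definite. Consequently the package's synthetic headline numbers land
*near* the published ones (multivariate AUC ≈ 0.80 vs 83; univariate
AUCs ≈ 0.61–0.78 vs 61–68) rather than on them, and passing tests
demonstrate correctness of the machinery under these declared
conditions, not recovery of the original cohort. Features of real data
the generator does not emulate: recruitment attrition, gestational-age
jitter within trimesters, non-normal biomarker tails, missing visits.

`generate_from_model()` is the second generator: it simulates *exactly*
from the mixed model (known $\beta, D, \Omega$, covariates redrawn), and
is what the parameter-recovery and covariance-fidelity tests use. With a
label-first class-conditional generator the equal-covariance model is
mildly misspecified (group-specific SDs); with `generate_from_model()`
it is exact.

## Numerical choices and degenerate inputs

* Stacking order is fixed (visits within biomarker) and every covariance
  assembly respects it.
* $D$ is kept positive semi-definite by construction (log-Cholesky);
  moment starts are eigenvalue-clipped before factorization.
* Ties: allocation at the exact threshold goes to non-GDM (the rule's
  $\ge$); Youden ties go to the lower threshold; AUC ties count ½.
* Degenerate evaluation inputs (single-class labels, < 2 per class for a
  CI, zero contingency marginals, singular $V$) raise informative
  errors; `validate_cohort()` reports rule violations without raising.
* CSV round trips are bit-exact: numerics are written with 17
  significant digits and stored as doubles.

## Problem sizes used by the test suite

Simulation-based checks are sized to be decisive yet quick: moment
fidelity at n = 50,000–200,000 subjects (3 Monte-Carlo-SE bands),
parameter recovery with 200 replicates of n = 2,000 (two-marker truth,
$k = 6$, so the per-component bias bound retains statistical meaning),
type-I-error calibration over 2,000 null replicates, and
information-pooling comparisons averaged over replicates of n = 5,000.
The full suite runs in about two minutes.

## Known limitations

* Two visits only; no serial correlation structures beyond the random
  intercept, no random slopes, no unbalanced designs beyond
  complete-case handling with a logged drop count.
* Two populations only; no quadratic discriminant (the rule assumes a
  common $V_i$).
* The mixed-design ANOVA covers the two-level within factor of this
  design; with more visits a sphericity correction would be required.
* Published p-values for parity/education are not reproducible from the
  published counts under the stated test; the package follows the test,
  not the printed values.
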