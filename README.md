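# gdmpanel

Early prediction of gestational diabetes mellitus (GDM) from routine
complete-blood-count biomarkers measured longitudinally in the first and
early second trimesters of pregnancy.

GDM is usually diagnosed only at 24–28 weeks, via a two-step procedure: a
50-g glucose load test (1-h plasma glucose ≥ 140 mg/dL triggers step two)
followed by a 100-g oral glucose tolerance test judged by the
Carpenter–Coustan criteria (positive when at least two of fasting ≥ 95,
1-h ≥ 180, 2-h ≥ 155, 3-h ≥ 140 mg/dL are met). By that point much of the
window for early intervention has closed. This package implements a
statistical screening strategy that uses four inexpensive biomarkers —
hemoglobin (Hb, g/dL), hematocrit (Hct, %), fasting blood sugar
(FBS, mg/dL) and red blood cell count (RBC, ×10¹²/L) — each measured at
two prenatal visits, to classify women as GDM or non-GDM months before
the diagnostic OGTT.

## The model and the allocation rule

For subject *i*, the four biomarkers at both visits are stacked into a
response vector **y**ᵢ of length *q* = 8 and modelled with a multivariate
longitudinal random-effects model

> **y**ᵢ = **X**ᵢ**β** + **Z**ᵢ**b**ᵢ + **ε**ᵢ,  **b**ᵢ ~ N(0, **D**),  **ε**ᵢ ~ N(0, **Ω**ᵢ)

with one random intercept per biomarker (unstructured 4×4 **D**),
biomarker-specific error variances, and fixed effects (per biomarker) for
the GDM indicator, visit, maternal age, BMI, SBP and DBP. After maximum
likelihood estimation, each woman is allocated by the linear discriminant
rule with marginal covariance **V**ᵢ = **Z**ᵢ**D****Z**ᵢ′ + **Ω**ᵢ:

> allocate to non-GDM iff (**μ**₁ᵢ − **μ**₂ᵢ)′ **V**ᵢ⁻¹ (**y**ᵢ − ½(**μ**₁ᵢ + **μ**₂ᵢ)) ≥ ln(π₂/π₁)

where **μ**_gᵢ is the subject's fitted mean under group *g* and π₁, π₂ are
the population proportions of non-GDM and GDM. Running the same machinery
on a single biomarker (*q* = 2) gives the univariate strategy; pooling all
four (*q* = 8) gives the multivariate strategy. Performance is evaluated
with ROC analysis: Mann–Whitney AUC, DeLong (or stratified-bootstrap)
confidence intervals, and named operating points ("bayes" at ln(π₂/π₁),
"youden" maximizing sens + spec − 1), both by resubstitution and by
stratified k-fold cross-validation.

Because the underlying patient-level cohort is not publicly deposited, the
package ships a seeded synthetic-cohort generator calibrated to the
published group × visit summary statistics (n = 600, GDM prevalence 8.2%),
so the entire analysis is reproducible end to end.

## Worked example

```r
library(gdmpanel)

cfg <- study_config(seed = 1, folds = 10)   # default calibrated cohort, n = 600
report <- run_study(cfg)
print(report)
```

```
Study report (simulated cohort, n = 600, GDM = 57)

       marker            mode sens spec auc    ci
           hb  resubstitution   44   76  61 53-69
          hct  resubstitution   60   64  64 57-71
          fbs  resubstitution   77   71  78 71-84
          rbc  resubstitution   86   42  65 58-71
 multivariate  resubstitution   75   75  80 74-86
           hb cross-validated   44   76  60 52-68
          hct cross-validated   58   64  63 56-70
          fbs cross-validated   65   82  77 71-84
          rbc cross-validated   74   54  64 58-71
 multivariate cross-validated   67   83  79 72-85
```

The printed sens/spec are the Youden operating point, in percent. The grid
shows the central finding the package reproduces on its synthetic cohort:
each biomarker alone is a weak longitudinal classifier (AUC ≈ 0.60–0.78),
while pooling the four repeated biomarkers in one multivariate
discriminant raises the AUC to ≈ 0.80, and the optimism of resubstitution
relative to 10-fold cross-validation is small at this sample size.
`write_study_report(report, "out/")` serializes the full-precision JSON
and a Markdown table; `describe_by_group()`, `mlmm_fit()`,
`classify_cohort()`, `cross_validate()`, `roc_curve()` and friends expose
every intermediate stage.

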