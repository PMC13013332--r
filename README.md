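# petkinetics

Tumor response kinetics from serial FDG-PET/CT biomarkers.

## The problem

In limited-disease small-cell lung cancer treated with induction chemotherapy
followed by concurrent radiochemotherapy, quantitative PET biomarkers —
SUVmax, metabolic tumor volume (MTV, mL), and total lesion glycolysis
(TLG = MTV × SUVmax) — are measured at a staging scan (usually *before* day 0,
the start of chemotherapy) and at an interim scan around day 86 acquired for
radiotherapy planning. Scan timing varies patient to patient, so simple
percent-change response criteria do not apply. `petkinetics` is for analysts
who want to model such irregularly-timed serial biomarkers, flag patients
whose late values sit implausibly far above the expected decay curve, and
test whether that flag predicts progression-free survival (PFS).

## The model

All patients share a mono-exponential decay with an asymptotic offset; each
patient has their own scale:

    y_i(t) = B_i · [ (1 − c) · e^(−λ t) + c ]

* `λ` (per day) — decay rate common to all patients; the half-time of
  decrease is `T½ = ln 2 / λ`.
* `c` ∈ (0, 1) — common asymptotic offset: the fraction of the baseline value
  at which the biomarker plateaus.
* `B_i` > 0 — patient-specific scale, equal to the model value at day 0.

The fit is unweighted nonlinear least squares over (λ, c, all `B_i`),
computed by variable projection: for fixed (λ, c) each `B_i` has the closed
form `Σ y f / Σ f²` with `f(t) = (1−c)e^(−λt) + c`, so the outer problem is
two-dimensional and is solved from a deterministic multi-start grid.

Pre-treatment scans are backdated onto the model time axis: SUVmax is assumed
constant over the short pre-treatment window (day −x → day 0), while for
MTV/TLG pre-treatment growth is assumed to mirror post-treatment shrinkage
(day −x → day +x, capped at day 21).

A patient is a **poor responder** when any observation after day 30 exceeds
the model-predicted mean by more than 2 standard deviations of the predicted
value. The flag is cross-tabulated against PFS events (Fisher's exact test,
binary-predictor AUC), groups are compared by Kaplan–Meier/log-rank, and the
flag is confirmed by leave-one-out cross-validation: shared parameters are
refit without the held-out patient, whose scale is then profiled from their
own observations.

Because no patient-level data ship with the package, a synthetic-cohort
generator (`simulate_cohort()`) reproduces the study's design — scan
schedule, lognormal baseline heterogeneity, a poor-responder minority with an
inflated plateau, multiplicative noise, and outcome linkage — with full
ground truth.

## Worked example

```r
library(petkinetics)
cfg <- sim_config(n_patients = 35, seed = 42)      # study-like cohort
sim <- simulate_cohort(cfg)
rep <- run_pipeline(sim$observations, sim$outcomes,
                    run_config(endpoints = "SUVMAX"))
cat(render_report(rep), sep = "\n")
```

```
== Tumor response kinetics report ==
Median follow-up (reverse KM): 41.0 months

-- SUVMAX --
half-time of decrease: 7.93 days (95% CI 3.50-Inf)
asymptotic offset: 0.446; R-squared: 0.8528
risk x PFS-event cross-tab (rows event no/yes, cols inlier/outlier):
  no : 18 0
  yes: 15 2
Fisher exact p = 0.2286
AUC = 0.56 (95% CI 0.48-0.64)
prevalence of risk flag: 5.7%; LOOCV-eligible: no
log-rank (flagged vs not): chisq = 9.97, p = 0.0016
Cox HR per unit baseline covariate: 1.042 (95% CI 0.981-1.106)
LOOCV: not eligible
```

The fitted half-time (7.93 days) is close to the generator truth of 8 days;
the offset is biased upward by the simulated poor responders. Both flagged
patients progressed (cross-tab), the flag's prevalence (5.7%) falls short of
the >15% variability required for LOOCV confirmation at this seed, and the
log-rank test separates the flagged group's PFS.

Lower-level entry points: `read_observations()` / `read_outcomes()` for CSV
cohorts, `adjust_cohort()`, `fit_decay()`, `half_time()`,
`classify_cohort()`, `fisher_exact_2x2()`, `binary_auc()`,
`kaplan_meier()`, `logrank_test()`, `cox_univariate()`, `loocv_run()`,
`write_fit()` / `read_fit()` for JSON fit artifacts.

## Vignette

`vignettes/tumor-response-kinetics.Rmd` documents the model and its
assumptions, every tunable parameter with its default and rationale, what
the synthetic generator does and does not emulate, numerical choices, and
known limitations (including the outlier-masking behavior of the 2-SD rule
at high contamination).
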