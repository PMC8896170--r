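# psndelay

Do physicians who routinely share patients deliver faster cancer care?
`psndelay` is an R package for studying **patient-sharing networks (PSNs)**
— diagnosing/treating physician dyads identified from administrative claims
— and their association with a **30-day delay in time to treatment
initiation (TTI)** among older colorectal-cancer patients. It is aimed at
health-services and cancer-care-delivery researchers who work with
Medicare-like claims (e.g. SEER-Medicare linkages) and want a tested,
reproducible implementation of the whole analysis chain, plus a calibrated
synthetic-claims generator for method validation where the real linkage is
access-restricted.

## The model

A dyad is an ordered pair (diagnosing provider *dx*, treating provider
*tx*) linked through at least one shared patient; a patient is *in a PSN*
when their dyad has shared at least 3 patients (the top quartile of
sharing; configurable 2–10, with a two-sample Kolmogorov–Smirnov check of
the cut point). The outcome is Y = **1**{TTI > 30 d}, modelled by weighted
multivariable logistic regression

logit P(Y=1) = β₀ + β₁·nonPSN + β₂ᵀ(patient factors) + β₃ᵀ(dyad factors),

with patient factors age band / gender / race-ethnicity / marital status /
poverty stratum / stage (1, 2, 3–4) / Charlson-Deyo comorbidity (0, 1, 2+)
and dyad factors gender pair (MM reference), facility colocation, and
dx/tx specialty category. Complete-case selection is corrected by
inverse-propensity weights from a logistic completeness model; standard
errors are HC0 sandwich; effects are reported as adjusted odds ratios
(AOR = exp β) with Wald 95% CIs and the model c-statistic.

The synthetic generator embeds *known* conditional odds ratios (defaults:
the published SEER-Medicare benchmark estimates, e.g. non-PSN 2.20,
non-colocated dyad 1.95, female–female dyad 0.66) in cohorts whose
marginals match that benchmark: mean TTI 17.3 d, overall delay ≈ 17%,
PSN prevalence 4.8%, dyad shared-count mean 1.2 (SD 0.47, median 1).

## Worked example

```r
library(psndelay)

ds  <- generate_cohort(sim_config(n_patients = 5000, seed = 42))
res <- run_delay_pipeline(ds)
res
```

```
Patient-sharing-network delay pipeline
  analytic population 5000 (complete cases modelled: 4609)
  PSN prevalence 4.38%, delay prevalence 17.10%, mean TTI 17.25 d
  KS (PSN vs non-PSN TTI): D = 0.083, p = 0.104

Multivariable odds of a 30-day treatment delay (C = 0.70; N = 4609)

  term                            AOR       95% CI  p
  psn: no_psn                    2.26   1.38-3.70   0.0013
  stage_group: 2                 0.76   0.64-0.91   0.0025
  stage_group: 3_4               0.52   0.41-0.66   <.0001
  ...
  colocation: not_colocated      1.77   1.46-2.16   <.0001
  tx_specialty: non_oncology     0.14   0.11-0.18   <.0001

  robust (HC0 sandwich) standard errors; inverse-propensity weighted
```

Patients outside a PSN have about 2.3 times the adjusted odds of a 30-day
delay in this simulated cohort (true embedded value 2.20); dyads split
across facilities also delay care. The generator drew 5,000 patients with
~7.5% missingness; the eligibility cascade, dyad construction, comorbidity
scoring, propensity weighting and weighted fit are all visible in `res`
(`res$report`, `res$dyads`, `res$propensity`, `tidy(res$fit)`,
`glance(res$fit)`). `autoplot(res$fit)` draws the AOR forest plot and
`autoplot(res$ks)` the PSN vs non-PSN TTI ECDFs. To run the same pipeline
on your own tables, point `run_delay_pipeline()` at a directory holding
`patients.csv`, `providers.csv`, `encounters.csv` (schemas in
`?read_dataset`).

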