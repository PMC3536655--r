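---
title: "LKB NTCP modelling of radiation-induced xerostomia: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LKB NTCP modelling of radiation-induced xerostomia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lkbntcp)
```

## The problem and the model

Irradiating the parotid glands during head-and-neck radiotherapy destroys
salivary function; the clinically relevant question is how the probability
of a defined toxicity endpoint — grade-3+ xerostomia one year after
treatment — rises with the dose the glands receive. The package models this
with the Lyman–Kutcher–Burman (LKB) normal tissue complication probability
model: a probit dose–response on the equivalent uniform dose,

$$\mathrm{NTCP} = \Phi(t), \qquad t = \frac{\mathrm{EUD} - TD_{50}}{m \cdot TD_{50}},
\qquad \mathrm{EUD} = \Big(\sum_i v_i D_i^{1/n}\Big)^{n}.$$

Assumptions worth stating explicitly:

* **Probit shape.** The response is the integrated normal distribution in
  dose. `ntcp()` evaluates it with the erf-based CDF (`stats::pnorm`),
  accurate to below 1e-12, rather than by numerical quadrature of the
  integral; the test suite keeps an independent quadrature oracle to pin the
  two together to 1e-8 over $t \in [-6, 6]$. A published "simplified" LKB
  variant that replaces the integral by an exponential of a quadratic in
  dose exists in the literature; it is deliberately not implemented — the
  exact probit is strictly better on every axis we care about.
* **Volume effect.** The parotid is treated as a parallel organ: `n = 1` by
  default everywhere, making the EUD the volume-weighted mean dose. The DVH
  machinery still supports arbitrary `n > 0`, and `fit_lkb()` offers an
  experimental free-`n` fit over per-gland DVH curves, but nothing in the
  default analysis depends on sub-gland dose heterogeneity.
* **Independence.** Glands (or patients, for patient-level endpoints) are
  independent Bernoulli observations. Within-patient correlation of the two
  glands' outcomes is not modelled — a real limitation for per-gland
  analyses, shared with the standard practice this package mirrors.

## Parameters

| parameter | units | default | meaning |
|---|---|---|---|
| `td50` | Gy | — (fit) | uniform dose at 50% complication probability |
| `m` | — | — (fit) | relative slope; smaller is steeper; floored at 1e-4 to avoid a degenerate step response |
| `n` | — | 1 | volume-effect exponent of the generalized-mean DVH reduction |

The published fits this package reproduces as worked examples are
TD50 = 43.6 Gy, m = 0.18 for the scintigraphic (SEF) endpoint and
TD50 = 44.1 Gy, m = 0.11 for the quality-of-life endpoint.

## Endpoints

The scintigraphic endpoint is the salivary excretion factor at one year
relative to baseline. `lentsoma_grade()` applies the LENT-SOMA salivary-flow
bands (grade 1: 76–95% of baseline, 2: 51–75%, 3: 26–50%, 4: 0–25%) with
boundary values assigned to the more severe grade — a single conservative
convention chosen because the printed integer-percent bands do not dictate
one. The primary binary endpoint `sef_event()` is flow ≤ 45% of baseline
(inclusive). Note the deliberate discrepancy: 45% is stricter than the 50%
upper edge of the grade-3 band, and the source study calls the 45% rule
"grade 3+"; both predicates are exposed rather than reconciled, with the 45%
rule as the default event definition.

The questionnaire endpoint binarizes the 4-level xerostomia item at
moderate-to-severe (score ≥ 3 of 4). The source study never prints its exact
item-level mapping, so the threshold is this package's declared convention.

Analysis units differ by endpoint: SEF is gland-level (62 evaluations for 31
patients), QoL is patient-level and is analysed against the spared
(lower-dose) gland's mean dose. Whether a per-gland or per-patient-spared
analysis is the right reading of the source material is genuinely ambiguous
— the gland counts say one thing, the figure axes another — so
`analysis_units()` makes both available and defaults differ per endpoint.

## Estimation and confidence intervals

`fit_lkb()` maximizes the Bernoulli likelihood of the individual
(dose, event) observations — not least squares on binned proportions;
binning is a display device only. The source study does not state its
objective or CI construction (a commercial statistics package was used), so
maximum likelihood with profile-likelihood intervals is this package's
declared choice; profile intervals behave better than Wald at the small
sample sizes involved.

Numerical choices:

* Optimization is on `(log TD50, log m)` with box bounds TD50 ∈ [5, 100] Gy,
  m ∈ [0.01, 1], via L-BFGS-B at a tight tolerance (`factr = 1e3`) from a
  fixed 3×3 multi-start grid (geometric 20/50/80% quantiles of each box), so
  a given input always yields the same fit. Among starts tying the best
  likelihood, one with a clean optimizer exit is preferred.
* Probabilities are clamped to `[1e-12, 1 − 1e-12]` inside the likelihood.
* Perfectly dose-separated outcomes push `m` to its lower box bound; the fit
  is returned flagged (`boundary`) with a warning instead of failing,
  mirroring separation behaviour in logistic regression.
* Single-class outcomes and single-dose designs are refused as
  non-identifiable.
* Profile CI bounds solve `2(ℓ_max − ℓ_profile(θ)) = χ²₁(level)` by
  bisection to a relative tolerance of 1e-4, re-maximizing the other
  parameter at each candidate via 1-D optimization. Bounds that run into the
  search box are returned at the box edge and flagged open-ended.

The intercept-only model used for `loglik_null` (and hence Nagelkerke R²) is
not nested in the LKB family — a constant response needs `m → ∞` — so for
dose-unresponsive data the LKB maximum can in principle fall below the null;
`nagelkerke_r2()` raises an error in that case rather than returning a
negative "variance explained".

## Performance metrics and guideline validation

* **Nagelkerke R²** from the model and null log-likelihoods.
* **AUC** by the Mann–Whitney estimator with ties counted 0.5; the tests pin
  it to an exhaustive pairwise enumeration.
* **Hosmer–Lemeshow** with 10 near-equal risk groups (the conventional
  deciles; the source never states its count), tied predictions kept
  together in the lower group, `df = groups − 2`, and groups with zero
  expected counts merged into a neighbour with a warning. The `groups − 2`
  rule presumes the model's parameters were estimated from the data being
  tested; the calibration-null simulations in the test suite therefore refit
  a correctly specified model per replicate — drawing labels from known
  probabilities without refitting inflates the statistic toward χ² with
  `groups` degrees of freedom and is not a correct null for this test.
* **Pearson 2×2 chi-squared** without continuity correction (the declared
  convention; the printed p-values cannot adjudicate it), used for the
  SEF-vs-QoL endpoint agreement. How the source formed that comparison from
  62 glands and 31 patients is unstated; this package compares the two
  per-patient endpoints (spared-gland SEF event vs QoL event) and documents
  that as its construction.
* **Spearman correlation** as Pearson on average ranks with the
  t-approximation p-value on `n − 2` df.
* **QUANTEC validation**: `classify_by_cutoff()` predicts no xerostomia at
  doses at or below the cutoff; PPV and NPV are computed from sensitivity,
  specificity and prevalence and equal the confusion-count ratios exactly
  whenever those are defined. The default cutoff panel {20, 25, 43.6,
  44.1} Gy pairs the two QUANTEC doses with the two fitted TD50 values.

## The synthetic-cohort generator

`simulate_cohort()` emulates the study conditions so every stage is testable
without patient data: 31 patients by default; ipsilateral/contralateral mean
doses from truncated normals matching the reported means and ranges
(51.7 Gy over 26.9–74.8; 36.7 Gy over 7.6–57.6), with SD = range/4 where
only a range is reported; baseline SEF from a truncated normal
(48.1% ± 18.2%, range 19.2–72.8); per-gland SEF events Bernoulli from the
LKB response at the gland dose; follow-up SEF drawn conditionally on the
event flag (flow ratio uniform on (0, 0.45) given an event, (0.45, 1.1)
otherwise) so the derived endpoint reproduces the generated events exactly;
per-patient QoL events from the LKB response at the spared-gland dose,
mapped to questionnaire scores. Ipsilateral–contralateral dose correlation
is unreported in the source, so the default is independence with a
Gaussian-copula correlation parameter available.

What it does **not** emulate — and therefore what passing tests do not show
about real data: within-patient correlation of gland outcomes; any
continuous dose–function relationship in the follow-up SEF beyond the binary
endpoint; covariate effects (age, site, surgery, chemotherapy); follow-up
attrition. One consequence of taking the published fit as the generative
truth deserves emphasis: at the reported dose distribution it implies a
per-gland event rate near 50%, far above the observed 16% — the published
parameters and the published per-gland counts are not mutually consistent,
presumably because the published curve was fitted against the spared-gland
dose axis. The generator is therefore a self-consistent stress-bench for the
estimation machinery, not a faithful replica of the observed cohort's event
counts; the patient-level QoL prevalence it produces (~20%) does match the
observed 19.4%.

## Problem sizes and reproducibility

All randomness flows from explicit integer seeds (`cohort_config(seed = )`,
`simulate_dvh(seed = )`), and the generator restores the caller's RNG state.
The validation suite exercises: 1000 random DVHs for the EUD/mean-dose
identity; parameter recovery and profile-CI coverage on 400 simulated
cohorts of 500 glands each (doses uniform on 10–70 Gy, truth
TD50 = 43.6 Gy, m = 0.18) — median bias within 0.5 Gy and 0.01, coverage
within 93–97%; and 500 replicates of the calibrated Hosmer–Lemeshow null at
200 observations. These sizes keep the full suite around a minute on one
CPU while leaving the Monte-Carlo noise well inside the asserted bands.

## Known limitations

* Only one follow-up time point is modelled; longitudinal recovery is out of
  scope.
* No alternative response shapes (logistic, log-logistic, relative
  seriality) and no Bayesian or bootstrap uncertainty.
* The free-`n` fit is experimental and has no profile CIs.
* DVHs are treated as point masses at bin doses (no within-bin
  interpolation) — negligible at the 0.01-Gy bin widths planning systems
  export, visible for coarse hand-made curves.
* DICOM-RT parsing is out of scope; DVHs and cohort tables enter as
  delimited text.
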