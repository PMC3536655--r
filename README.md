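# lkbntcp

Normal tissue complication probability (NTCP) modelling of
radiation-induced xerostomia (dry mouth) after head-and-neck radiotherapy.

Sparing the parotid glands is the main lever for preventing chronic
xerostomia in head-and-neck cancer patients treated with IMRT. This package
provides the statistical toolchain a clinical physicist or outcomes
researcher needs to relate parotid mean dose to the probability of losing
salivary function: the Lyman–Kutcher–Burman (LKB) dose–response model,
maximum-likelihood estimation of its parameters from per-gland or
per-patient outcome data, derivation of the toxicity endpoints themselves
from salivary scintigraphy and quality-of-life questionnaires, validation of
the QUANTEC 20/25-Gy planning guidelines by predictive values, and the usual
battery of model-performance statistics.

## The model

The LKB model assumes a probit (integrated-normal) dose–response on the
equivalent uniform dose:

    NTCP = Φ(t),    t = (EUD − TD50) / (m · TD50)

    EUD  = ( Σᵢ vᵢ · Dᵢ^(1/n) )^n

where `Φ` is the standard-normal CDF, `TD50` is the uniform dose giving a
50% complication probability, `m` sets the slope (smaller is steeper), and
`n` is the volume-effect exponent of the generalized-mean DVH reduction —
`n = 1` makes the EUD the mean dose, the conventional choice for the parotid
as a parallel organ. Parameters `(TD50, m)` are estimated by Bernoulli
maximum likelihood on individual (dose, event) observations, with
profile-likelihood confidence intervals.

Endpoints: the scintigraphic endpoint is a salivary excretion factor (SEF)
at or below 45% of the pre-treatment value one year after radiotherapy
(grade 3+ xerostomia on the LENT-SOMA salivary-flow bands); the
questionnaire endpoint is moderate-to-severe self-reported xerostomia.
QUANTEC guideline validation classifies patients by whether the spared
(lower-dose) parotid exceeds a dose cutoff and summarises agreement with the
observed events as PPV/NPV.

## Worked example

Evaluate the published SEF dose–response fit (TD50 = 43.6 Gy, m = 0.18,
n = 1) at the two QUANTEC cutoff doses and at the TD50 itself:

```r
library(lkbntcp)
params <- lkb_params(td50 = 43.6, m = 0.18)
round(100 * ntcp(c(20, 25, 43.6), params), 2)
#> [1]  0.13  0.89 50.00
```

A mean dose of 20 Gy to the spared gland carries a 0.13% modelled risk of
grade-3+ xerostomia, 25 Gy carries 0.89% — both comfortably below the ~1%
and ~2% incidences reported at those cutoffs — and at 43.6 Gy the risk is
50% by definition of TD50.

The full pipeline on a synthetic 31-patient cohort emulating the study's
dose and salivary-function distributions:

```r
report <- run_pipeline(cohort_config(n_patients = 31, seed = 1))
print(report)
#> NTCP analysis report (lkbntcp 0.1.0)
#>   cohort: 31 patients, 62 glands (seed 1)
#>
#> == SEF endpoint (62 units, 32 events) ==
#>   TD50 = 44.75 Gy, m = 0.1430  [TD50 41.6-47.8 Gy; m 0.093-0.232]
#>   Nagelkerke R2 = 0.735, AUC = 0.943, H-L chi2 = 8.34 (df 8, p = 0.401)
#>   cutoff 20.0 Gy: PPV 52.5%, NPV 100.0%
#>   cutoff 25.0 Gy: PPV 54.2%, NPV 100.0%
#>   cutoff 43.6 Gy: PPV 82.4%, NPV 85.7%
#>   cutoff 44.1 Gy: PPV 82.4%, NPV 85.7%
#>
#> == QOL endpoint (31 units, 7 events) ==
#>   TD50 = 43.07 Gy, m = 0.0606  [TD50 40.6-46.8 Gy; m 0.027-0.158]
#>   Nagelkerke R2 = 0.811, AUC = 0.976, H-L chi2 = 3.76 (df 8, p = 0.878)
#>   cutoff 20.0 Gy: PPV 23.3%, NPV 100.0%
#>   cutoff 25.0 Gy: PPV 25.0%, NPV 100.0%
#>   cutoff 43.6 Gy: PPV 85.7%, NPV 95.8%
#>   cutoff 44.1 Gy: PPV 85.7%, NPV 95.8%
#>
#> SEF vs QoL endpoint agreement: chi2 = 25.99, p = 0.000
```

The simulated cohort is generated from a true LKB response (TD50 = 43.6 Gy,
m = 0.18 for SEF; 44.1 Gy, 0.11 for QoL at the spared-gland dose); the fit
recovers those parameters within its confidence intervals, and because no
event falls below 25 Gy the QUANTEC cutoffs achieve 100% NPV — the
guideline's headline property.

Real data enter through `read_cohort()` (per-gland CSV/TSV of doses and
salivary/QoL measurements) and `read_dvh()` (two-column dose–volume tables,
differential or cumulative), with `eud()`/`mean_dose()` reducing DVHs to the
dose axis the model uses.

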