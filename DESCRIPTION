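Package: lkbntcp
Title: Lyman-Kutcher-Burman NTCP Modelling of Radiation-Induced Xerostomia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Normal tissue complication probability (NTCP) analysis for
    radiation-induced xerostomia of the parotid glands. Implements the
    Lyman-Kutcher-Burman probit dose-response model on the equivalent
    uniform dose (EUD), reduction of dose-volume histograms to EUD and
    mean dose, maximum-likelihood estimation of the TD50 and slope (m)
    parameters from binary complication data with profile-likelihood
    confidence intervals, LENT-SOMA salivary-flow grading and
    quality-of-life endpoint derivation, validation of the QUANTEC
    20/25-Gy parotid mean-dose guidelines via predictive values
    (PPV/NPV), model-performance metrics (Nagelkerke R-squared, AUC,
    Hosmer-Lemeshow calibration, Pearson chi-squared, Spearman
    correlation), and a synthetic-cohort generator emulating the dose
    and salivary-function distributions of a head-and-neck IMRT cohort.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
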