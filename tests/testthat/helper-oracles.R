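# Independent oracles used across the suite. These deliberately use
# different routes than the package implementation.

# standard-normal CDF by literal quadrature of the probit integrand
quadrature_normal_cdf <- function(t) {
  stats::integrate(function(x) exp(-x^2 / 2) / sqrt(2 * pi),
                   lower = -Inf, upper = t,
                   rel.tol = 1e-12, abs.tol = 1e-13)$value
}

# AUC by exhaustive enumeration of all positive-negative pairs
auc_bruteforce <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Bernoulli negative log-likelihood by plain elementwise summation
negloglik_bruteforce <- function(td50, m, dose, event) {
  out <- 0
  for (i in seq_along(dose)) {
    p <- stats::pnorm((dose[i] - td50) / (m * td50))
    p <- min(max(p, 1e-12), 1 - 1e-12)
    out <- out - (event[i] * log(p) + (1 - event[i]) * log(1 - p))
  }
  out
}

# random valid differential DVH curve
random_dvh <- function(k = sample(2:30, 1)) {
  d <- sort(stats::runif(k, 0.1, 80))
  while (any(diff(d) <= 0)) d <- sort(stats::runif(k, 0.1, 80))
  v <- stats::rexp(k)
  dvh_curve(d, v / sum(v))
}

# cohort table fixture: n patients, two glands each, optional measurements
toy_cohort_df <- function(n = 5, seed = 99) {
  set.seed(seed)
  data.frame(
    patient_id = rep(sprintf("P%02d", seq_len(n)), each = 2),
    laterality = rep(c("ipsilateral", "contralateral"), n),
    mean_dose_gy = round(stats::runif(2 * n, 10, 70), 3),
    baseline_sef = round(stats::runif(2 * n, 30, 70), 3),
    followup_sef = round(stats::runif(2 * n, 5, 70), 3),
    qol_score = rep(sample(1:4, n, replace = TRUE), each = 2),
    stringsAsFactors = FALSE
  )
}
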