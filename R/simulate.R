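#' Configuration of a synthetic parotid cohort
#'
#' Defaults reproduce the study conditions of a 31-patient head-and-neck
#' IMRT cohort: ipsilateral gland mean doses averaging 51.7 Gy over
#' 26.9-74.8 Gy, contralateral 36.7 Gy over 7.6-57.6 Gy, baseline salivary
#' excretion factor normally distributed with mean 48.1% and SD 18.2% over
#' 19.2-72.8%, SEF events generated from an LKB dose-response with
#' TD50 = 43.6 Gy, m = 0.18, and patient-level QoL events from the
#' spared-gland dose with TD50 = 44.1 Gy, m = 0.11. Dose marginals are
#' truncated normals on the stated ranges with SD = range/4 where the SD is
#' otherwise unspecified.
#'
#' @param n_patients Number of patients (2 glands each).
#' @param ipsi_dose,contra_dose,baseline_sef Lists with elements `mean`,
#'   `sd` and `range = c(lo, hi)` describing a truncated normal.
#' @param true_params_sef,true_params_qol `lkb_params` driving per-gland SEF
#'   events and per-patient QoL events respectively.
#' @param dose_correlation Gaussian-copula correlation between a patient's
#'   ipsilateral and contralateral doses (default 0: independent; the source
#'   study does not report this correlation).
#' @param seed Integer RNG seed; the whole cohort is reproducible from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(
    n_patients = 31,
    ipsi_dose = list(mean = 51.7, sd = (74.8 - 26.9) / 4,
                     range = c(26.9, 74.8)),
    contra_dose = list(mean = 36.7, sd = (57.6 - 7.6) / 4,
                       range = c(7.6, 57.6)),
    baseline_sef = list(mean = 48.1, sd = 18.2, range = c(19.2, 72.8)),
    true_params_sef = lkb_params(td50 = 43.6, m = 0.18),
    true_params_qol = lkb_params(td50 = 44.1, m = 0.11),
    dose_correlation = 0,
    seed = 1L) {
  if (!is.numeric(n_patients) || n_patients < 1)
    stop("'n_patients' must be >= 1")
  for (nm in c("ipsi_dose", "contra_dose", "baseline_sef")) {
    b <- get(nm)
    if (!all(c("mean", "sd", "range") %in% names(b)))
      stop(sprintf("'%s' needs elements mean, sd, range", nm))
    if (b$sd <= 0) stop(sprintf("'%s$sd' must be > 0", nm))
    if (b$range[1] > b$mean || b$range[2] < b$mean)
      stop(sprintf("'%s' range must contain its mean", nm))
    if (b$range[2] < b$mean - 6 * b$sd || b$range[1] > b$mean + 6 * b$sd)
      stop(sprintf("'%s' truncation range excludes mean +/- 6 sd", nm))
  }
  if (!inherits(true_params_sef, "lkb_params") ||
      !inherits(true_params_qol, "lkb_params"))
    stop("true parameters must be lkb_params objects")
  if (abs(dose_correlation) >= 1)
    stop("'dose_correlation' must lie in (-1, 1)")
  structure(list(
    n_patients = as.integer(n_patients), ipsi_dose = ipsi_dose,
    contra_dose = contra_dose, baseline_sef = baseline_sef,
    true_params_sef = true_params_sef, true_params_qol = true_params_qol,
    dose_correlation = dose_correlation, seed = as.integer(seed)
  ), class = "cohort_config")
}

# inverse-CDF sampling of a truncated normal from given uniforms
.qtruncnorm <- function(u, spec) {
  plo <- stats::pnorm(spec$range[1], spec$mean, spec$sd)
  phi <- stats::pnorm(spec$range[2], spec$mean, spec$sd)
  stats::qnorm(plo + u * (phi - plo), spec$mean, spec$sd)
}

#' Simulate a parotid-gland cohort
#'
#' Per patient, ipsilateral and contralateral mean doses are drawn from
#' truncated normals (optionally copula-correlated); per gland, a baseline
#' SEF is drawn from its truncated normal and a binary SEF event from the
#' LKB dose-response at the gland dose. The follow-up SEF is then generated
#' conditionally on the event flag -- flow ratio uniform on (0, 0.45) given
#' an event, on (0.45, 1.1) otherwise -- so the binary endpoint derived from
#' the flow measurements reproduces the generated events exactly. A
#' patient-level QoL event is drawn from the LKB response at the spared-gland
#' dose and mapped to a 1-4 xerostomia score (3-4 for events, 1-2 otherwise).
#'
#' The caller's RNG state is left untouched; everything derives from
#' `config$seed`.
#'
#' @param config A `cohort_config`.
#' @return A `parotid_cohort` of `2 * n_patients` glands, with an attribute
#'   `sim_truth` holding the generated event flags and the config.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) stop("'config' must be a cohort_config")
  rng <- .with_seed(config$seed)
  on.exit(rng())

  np <- config$n_patients
  rho <- config$dose_correlation
  z1 <- stats::rnorm(np)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(np)
  ipsi <- .qtruncnorm(stats::pnorm(z1), config$ipsi_dose)
  contra <- .qtruncnorm(stats::pnorm(z2), config$contra_dose)

  dose <- as.numeric(rbind(ipsi, contra))       # gland order: ipsi, contra
  laterality <- rep(c("ipsilateral", "contralateral"), np)
  patient_id <- rep(sprintf("P%04d", seq_len(np)), each = 2L)

  ng <- 2L * np
  baseline <- .qtruncnorm(stats::runif(ng), config$baseline_sef)
  p_sef <- ntcp(dose, config$true_params_sef)
  event_sef <- stats::rbinom(ng, 1L, p_sef) == 1L
  ratio <- ifelse(event_sef, stats::runif(ng, 0, 0.45),
                  stats::runif(ng, 0.45, 1.1))
  followup <- ratio * baseline

  spared <- pmin(ipsi, contra)
  p_qol <- ntcp(spared, config$true_params_qol)
  event_qol <- stats::rbinom(np, 1L, p_qol) == 1L
  qol_score <- ifelse(event_qol,
                      sample(3:4, np, replace = TRUE),
                      sample(1:2, np, replace = TRUE))

  df <- data.frame(
    patient_id = patient_id,
    laterality = laterality,
    mean_dose_gy = dose,
    baseline_sef = baseline,
    followup_sef = followup,
    qol_score = rep(qol_score, each = 2L),
    stringsAsFactors = FALSE
  )
  cohort <- as_cohort(df)
  attr(cohort, "sim_truth") <- list(event_sef = event_sef,
                                    event_qol = event_qol,
                                    config = config)
  cohort
}

# seed the RNG for a scoped block; returns a restore function
.with_seed <- function(seed) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

#' Simulate a differential DVH curve with an exact mean dose
#'
#' Doses are sampled around `target_mean` with the requested spread, volumes
#' from normalized exponential weights, and the dose axis is rescaled so the
#' volume-weighted mean equals `target_mean` (to within floating-point
#' rounding). With `spread = 0` (or one bin) the curve is a single bin at
#' `target_mean`.
#'
#' @param target_mean Target mean dose in Gy, > 0.
#' @param spread Dose spread (SD) in Gy, >= 0.
#' @param bins Number of bins, >= 1.
#' @param seed Optional integer seed.
#' @return A differential `dvh_curve`.
#' @export
simulate_dvh <- function(target_mean, spread, bins = 100, seed = NULL) {
  if (!is.numeric(target_mean) || target_mean <= 0)
    stop("'target_mean' must be > 0")
  if (!is.numeric(spread) || spread < 0) stop("'spread' must be >= 0")
  if (!is.numeric(bins) || bins < 1) stop("'bins' must be >= 1")
  if (!is.null(seed)) {
    rng <- .with_seed(seed)
    on.exit(rng())
  }
  if (spread == 0 || bins == 1L)
    return(dvh_curve(target_mean, 1, form = "differential"))

  d <- .qtruncnorm(stats::runif(bins),
                   list(mean = target_mean, sd = spread,
                        range = c(max(target_mean - 4 * spread, 1e-6),
                                  target_mean + 4 * spread)))
  d <- sort(d)
  v <- stats::rexp(bins)
  # collapse accidental duplicate doses, keeping volumes
  if (anyDuplicated(d)) {
    v <- as.numeric(tapply(v, d, sum))
    d <- sort(unique(d))
  }
  v <- v / sum(v)
  d <- d * (target_mean / sum(v * d))
  dvh_curve(d, v, form = "differential")
}
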