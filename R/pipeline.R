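#' Run the full NTCP analysis pipeline
#'
#' Orchestrates cohort acquisition (simulation from a [cohort_config()], an
#' existing `parotid_cohort`, or a file path), endpoint derivation, LKB
#' maximum-likelihood fitting, model-performance evaluation and
#' predictive-value validation of the dose cutoffs, for both the SEF and QoL
#' endpoints. Every number in the report comes from the corresponding
#' module function on the same units; given a seeded config the report is
#' reproducible apart from its timestamp.
#'
#' @param config A `cohort_config` (simulate), a `parotid_cohort`, or a path
#'   to a cohort file.
#' @param endpoints Character subset of `c("sef", "qol")`.
#' @param cutoffs Dose cutoffs (Gy) for the predictive-value table; defaults
#'   to the two QUANTEC doses and the two fitted TD50 values.
#' @param hl_groups Risk-group count for the Hosmer-Lemeshow test.
#' @return An object of class `ntcp_run_report`: per-endpoint fits,
#'   performance blocks and predictive-value tables, the endpoint-agreement
#'   chi-squared on shared patients, and provenance (seed, counts, package
#'   version, timestamp).
#' @export
run_pipeline <- function(config, endpoints = c("sef", "qol"),
                         cutoffs = c(20, 25, 43.6, 44.1), hl_groups = 10) {
  endpoints <- match.arg(endpoints, c("sef", "qol"), several.ok = TRUE)

  seed <- NA_integer_
  if (inherits(config, "cohort_config")) {
    cohort <- simulate_cohort(config)
    seed <- config$seed
  } else if (inherits(config, "parotid_cohort")) {
    cohort <- config
  } else if (is.character(config) && length(config) == 1L) {
    cohort <- read_cohort(config)
  } else {
    stop("'config' must be a cohort_config, a parotid_cohort, or a file path")
  }

  message(sprintf("pipeline: %d patients, %d glands",
                  length(unique(cohort$patient_id)), nrow(cohort)))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  results <- list()
  for (ep in endpoints) {
    units <- stage(paste0("units:", ep), analysis_units(cohort, endpoint = ep))
    fit <- stage(paste0("fit:", ep), fit_lkb(units))
    pred <- ntcp(units$dose, fit$params)
    perf <- stage(paste0("evaluate:", ep), list(
      nagelkerke_r2 = nagelkerke_r2(fit$loglik, fit$loglik_null, fit$n_obs),
      auc = auc(pred, units$event),
      hosmer_lemeshow = hosmer_lemeshow(pred, units$event,
                                        groups = hl_groups)
    ))
    pv <- stage(paste0("quantec:", ep),
                predictive_values_at_cutoffs(units, cutoffs))
    message(sprintf("pipeline[%s]: %d units, %d events; TD50=%.2f Gy m=%.3f",
                    ep, nrow(units), sum(units$event),
                    fit$params$td50, fit$params$m))
    results[[ep]] <- list(units = units, fit = fit, performance = perf,
                          predictive_values = pv)
  }

  # endpoint agreement on shared patients: spared-gland SEF event vs QoL event
  agreement <- NULL
  if (all(c("sef", "qol") %in% endpoints)) {
    sef_pat <- tryCatch(
      analysis_units(cohort, "sef", unit = "per_patient_spared"),
      error = function(e) NULL)
    qol_pat <- tryCatch(
      analysis_units(cohort, "qol", unit = "per_patient_spared"),
      error = function(e) NULL)
    if (!is.null(sef_pat) && !is.null(qol_pat) &&
        nrow(sef_pat) == nrow(qol_pat)) {
      tab <- table(factor(sef_pat$event, levels = c(FALSE, TRUE)),
                   factor(qol_pat$event, levels = c(FALSE, TRUE)))
      agreement <- tryCatch(
        c(pearson_chi2_2x2(tab), list(table = tab)),
        error = function(e) list(table = tab, note = conditionMessage(e)))
    }
  }

  structure(list(
    results = results,
    agreement = agreement,
    provenance = list(
      seed = seed,
      n_patients = length(unique(cohort$patient_id)),
      n_glands = nrow(cohort),
      cutoffs = cutoffs,
      package_version = as.character(utils::packageVersion("lkbntcp")),
      timestamp = format(Sys.time(), tz = "UTC")
    )
  ), class = "ntcp_run_report")
}

#' @export
print.ntcp_run_report <- function(x, ...) {
  pv <- x$provenance
  cat(sprintf("NTCP analysis report (lkbntcp %s)\n", pv$package_version))
  cat(sprintf("  cohort: %d patients, %d glands (seed %s)\n",
              pv$n_patients, pv$n_glands, pv$seed))
  for (ep in names(x$results)) {
    r <- x$results[[ep]]
    cat(sprintf("\n== %s endpoint (%d units, %d events) ==\n",
                toupper(ep), nrow(r$units), sum(r$units$event)))
    cat(sprintf("  TD50 = %.2f Gy, m = %.4f", r$fit$params$td50,
                r$fit$params$m))
    if (!is.null(r$fit$ci))
      cat(sprintf("  [TD50 %.1f-%.1f Gy; m %.3f-%.3f]",
                  r$fit$ci$td50[1], r$fit$ci$td50[2],
                  r$fit$ci$m[1], r$fit$ci$m[2]))
    cat("\n")
    cat(sprintf("  Nagelkerke R2 = %.3f, AUC = %.3f, H-L chi2 = %.2f (df %d, p = %.3f)\n",
                r$performance$nagelkerke_r2, r$performance$auc,
                r$performance$hosmer_lemeshow$chi2,
                r$performance$hosmer_lemeshow$df,
                r$performance$hosmer_lemeshow$p))
    tab <- r$predictive_values
    for (i in seq_len(nrow(tab)))
      cat(sprintf("  cutoff %.1f Gy: PPV %s, NPV %s\n", tab$cutoff_gy[i],
                  .fmt_pct(tab$ppv[i]), .fmt_pct(tab$npv[i])))
  }
  if (!is.null(x$agreement) && !is.null(x$agreement$chi2))
    cat(sprintf("\nSEF vs QoL endpoint agreement: chi2 = %.2f, p = %.3f\n",
                x$agreement$chi2, x$agreement$p))
  invisible(x)
}

.fmt_pct <- function(p) if (is.na(p)) "undefined" else sprintf("%.1f%%", 100 * p)
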