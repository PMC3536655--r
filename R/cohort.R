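#' Validate and derive a parotid-gland cohort table
#'
#' Takes a per-gland data.frame and returns a validated cohort with derived
#' endpoint columns. Required columns: `patient_id`, `laterality`
#' ("ipsilateral"/"contralateral"), `mean_dose_gy`. Optional: `baseline_sef`,
#' `followup_sef` (percent; the SEF event is derived from their ratio),
#' `event` (logical, used as the SEF event when flow measurements are
#' absent), and `qol_score` (patient-level ordinal 1..4, constant within a
#' patient).
#'
#' Derived columns: `flow_ratio`, `event_sef`, `event_qol`, and
#' `spared_dose_gy` (the minimum gland mean dose within each patient).
#' Glands with missing follow-up are kept but their `event_sef` is `NA`;
#' they are excluded (with a message) when analysis units are extracted.
#'
#' @param df A data.frame, one row per gland.
#' @return A `parotid_cohort` (a classed data.frame).
#' @export
as_cohort <- function(df) {
  if (!is.data.frame(df)) stop("'df' must be a data.frame")
  req <- c("patient_id", "laterality", "mean_dose_gy")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0L)
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$patient_id <- as.character(df$patient_id)

  if (nrow(df) > 0L) {
    if (!all(df$laterality %in% c("ipsilateral", "contralateral")))
      stop("'laterality' must be 'ipsilateral' or 'contralateral'")
    if (any(!is.finite(df$mean_dose_gy)) || any(df$mean_dose_gy < 0))
      stop("'mean_dose_gy' must be non-negative and finite")
    if (anyDuplicated(df[, c("patient_id", "laterality")]))
      stop("duplicate (patient_id, laterality) rows")
    if (any(table(df$patient_id) > 2L))
      stop("more than two glands for a patient")
  }

  n <- nrow(df)
  df$flow_ratio <- rep(NA_real_, n)
  df$event_sef <- rep(NA, n)
  if (all(c("baseline_sef", "followup_sef") %in% names(df)) && n > 0L) {
    ok <- is.finite(df$baseline_sef) & is.finite(df$followup_sef)
    if (any(ok)) {
      df$flow_ratio[ok] <- flow_ratio(df$baseline_sef[ok], df$followup_sef[ok])
      df$event_sef[ok] <- sef_event(df$flow_ratio[ok])
    }
  } else if ("event" %in% names(df) && n > 0L) {
    df$event_sef <- as.logical(df$event)
  }

  df$event_qol <- rep(NA, n)
  if ("qol_score" %in% names(df) && n > 0L) {
    ok <- is.finite(df$qol_score)
    if (any(ok)) df$event_qol[ok] <- qol_event(df$qol_score[ok])
    # qol is a patient-level measurement: must not differ within a patient
    per_pat <- tapply(df$qol_score, df$patient_id,
                      function(s) length(unique(s[is.finite(s)])))
    if (any(per_pat > 1L, na.rm = TRUE))
      stop("'qol_score' differs between glands of the same patient")
  }

  df$spared_dose_gy <- if (n > 0L)
    stats::ave(df$mean_dose_gy, df$patient_id, FUN = min) else numeric(0)

  class(df) <- c("parotid_cohort", "data.frame")
  df
}

#' Read a parotid-gland cohort from delimited text
#'
#' Comma- or tab-delimited text with a header row; see [as_cohort()] for the
#' column contract and derived fields.
#'
#' @param path Path to the file.
#' @return A `parotid_cohort`.
#' @export
read_cohort <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  as_cohort(df)
}

#' Write a cohort's raw columns to delimited text
#'
#' Writes the measurement columns (not the derived ones) as CSV with full
#' floating-point precision, so that a write/read round trip preserves all
#' finite values bit-exactly.
#'
#' @param cohort A `parotid_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  if (!inherits(cohort, "parotid_cohort")) stop("'cohort' must be a parotid_cohort")
  raw_cols <- intersect(
    c("patient_id", "laterality", "mean_dose_gy",
      "baseline_sef", "followup_sef", "qol_score"),
    names(cohort)
  )
  out <- cohort[, raw_cols, drop = FALSE]
  for (cl in raw_cols) {
    if (is.double(out[[cl]])) {
      s <- sprintf("%.17g", out[[cl]])
      s[!is.finite(out[[cl]])] <- NA
      out[[cl]] <- s
    }
  }
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract (dose, event) analysis units from a cohort
#'
#' The SEF endpoint is analysed per gland by default (each gland contributes
#' its own mean dose and flow-derived event); the QoL endpoint per patient by
#' default, using the spared (lower-dose) gland's mean dose, matching an
#' analysis of patient-level xerostomia against the spared-gland dose. Both
#' units are available for both endpoints.
#'
#' Observations with a missing event for the requested endpoint are dropped
#' with a message stating the count.
#'
#' @param cohort A `parotid_cohort`.
#' @param endpoint `"sef"` or `"qol"`.
#' @param unit `"per_gland"` or `"per_patient_spared"`; default depends on
#'   the endpoint as above.
#' @return A data.frame with columns `dose` (Gy) and `event` (logical).
#' @export
analysis_units <- function(cohort, endpoint = c("sef", "qol"), unit = NULL) {
  if (!inherits(cohort, "parotid_cohort")) stop("'cohort' must be a parotid_cohort")
  endpoint <- match.arg(endpoint)
  if (is.null(unit))
    unit <- if (endpoint == "sef") "per_gland" else "per_patient_spared"
  unit <- match.arg(unit, c("per_gland", "per_patient_spared"))

  if (nrow(cohort) == 0L)
    return(data.frame(dose = numeric(0), event = logical(0)))

  ev_col <- if (endpoint == "sef") "event_sef" else "event_qol"
  if (all(is.na(cohort[[ev_col]])))
    stop(sprintf("no '%s' endpoint data in this cohort", endpoint))

  if (unit == "per_gland") {
    dose <- cohort$mean_dose_gy
    event <- cohort[[ev_col]]
  } else {
    # one unit per patient at the spared-gland dose; the event comes from
    # the spared gland itself (SEF) or the patient-level record (QoL)
    spared_idx <- tapply(seq_len(nrow(cohort)), cohort$patient_id,
                         function(i) i[which.min(cohort$mean_dose_gy[i])])
    spared_idx <- unlist(spared_idx, use.names = FALSE)
    dose <- cohort$mean_dose_gy[spared_idx]
    event <- cohort[[ev_col]][spared_idx]
  }

  keep <- !is.na(event)
  if (any(!keep))
    message(sum(!keep), " unit(s) without a ", endpoint,
            " endpoint excluded from analysis")
  data.frame(dose = dose[keep], event = as.logical(event[keep]))
}
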