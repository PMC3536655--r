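#' Does a treatment plan meet the QUANTEC parotid guideline?
#'
#' The guideline is met when at least one parotid gland receives a mean dose
#' of 20 Gy or less, or both glands receive 25 Gy or less. Boundary doses
#' count as meeting the guideline (<= semantics).
#'
#' @param gland_doses Numeric vector of 1 or 2 gland mean doses (Gy).
#' @return Logical.
#' @examples
#' meets_quantec(c(18, 60))  # TRUE: one gland spared below 20 Gy
#' meets_quantec(c(22, 30))  # FALSE
#' @export
meets_quantec <- function(gland_doses) {
  if (length(gland_doses) < 1L || length(gland_doses) > 2L)
    stop("'gland_doses' must hold 1 or 2 doses")
  if (any(!is.finite(gland_doses)) || any(gland_doses < 0))
    stop("doses must be non-negative")
  min(gland_doses) <= 20 || max(gland_doses) <= 25
}

#' Classify a dose against a cutoff
#'
#' Doses at or below the cutoff predict the absence of xerostomia (negative
#' classification); doses strictly above predict its presence.
#'
#' @param dose Dose(s) in Gy, >= 0.
#' @param cutoff Cutoff in Gy, > 0.
#' @return Logical: predicted positive (event expected)?
#' @export
classify_by_cutoff <- function(dose, cutoff) {
  if (any(!is.finite(dose)) || any(dose < 0)) stop("'dose' must be >= 0")
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop("'cutoff' must be a single positive dose")
  dose > cutoff
}

#' Confusion counts of a binary classification
#'
#' @param predicted Logical predicted-positive indicators.
#' @param observed Logical observed events.
#' @return An object of class `confusion_counts` with fields `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
confusion_counts <- function(predicted, observed) {
  predicted <- as.logical(predicted)
  observed <- as.logical(observed)
  if (length(predicted) != length(observed)) stop("length mismatch")
  if (length(predicted) == 0L) stop("empty classification")
  structure(list(
    tp = sum(predicted & observed),
    fp = sum(predicted & !observed),
    tn = sum(!predicted & !observed),
    fn = sum(!predicted & observed)
  ), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion counts: tp=%d fp=%d tn=%d fn=%d\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Positive predictive value from sensitivity, specificity and prevalence
#'
#' `sens*prev / (sens*prev + (1-spec)*(1-prev))`. Returns `NA` with a
#' warning when the denominator is zero (no positive classifications).
#'
#' @param sensitivity,specificity,prevalence Probabilities in \[0, 1\].
#' @return PPV in \[0, 1\], or `NA` when undefined.
#' @export
ppv <- function(sensitivity, specificity, prevalence) {
  .check_prob(sensitivity, specificity, prevalence)
  num <- sensitivity * prevalence
  den <- num + (1 - specificity) * (1 - prevalence)
  if (den == 0) {
    warning("PPV undefined: no positive classifications expected")
    return(NA_real_)
  }
  num / den
}

#' Negative predictive value from sensitivity, specificity and prevalence
#'
#' `spec*(1-prev) / ((1-sens)*prev + spec*(1-prev))`. Returns `NA` with a
#' warning when the denominator is zero.
#'
#' @inheritParams ppv
#' @return NPV in \[0, 1\], or `NA` when undefined.
#' @export
npv <- function(sensitivity, specificity, prevalence) {
  .check_prob(sensitivity, specificity, prevalence)
  num <- specificity * (1 - prevalence)
  den <- (1 - sensitivity) * prevalence + num
  if (den == 0) {
    warning("NPV undefined: no negative classifications expected")
    return(NA_real_)
  }
  num / den
}

.check_prob <- function(...) {
  vals <- c(...)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1))
    stop("sensitivity, specificity and prevalence must lie in [0, 1]")
  invisible(TRUE)
}

#' Predictive values of dose cutoffs against observed events
#'
#' For each cutoff, units are classified by [classify_by_cutoff()] and
#' tallied against the observed events. PPV and NPV are computed from
#' sensitivity, specificity and prevalence; these equal the direct count
#' ratios `tp/(tp+fp)` and `tn/(tn+fn)` whenever those are defined.
#' Undefined values (no predicted positives or negatives, or no events) are
#' reported as `NA`.
#'
#' The default cutoff panel holds the two QUANTEC doses and the two fitted
#' TD50 values from the SEF and QoL dose-response models.
#'
#' @param units A data.frame with columns `dose` (Gy) and `event` (logical),
#'   e.g. from [analysis_units()].
#' @param cutoffs Numeric vector of dose cutoffs in Gy.
#' @return A data.frame with one row per cutoff: counts, sensitivity,
#'   specificity, prevalence, `ppv` and `npv` (proportions in \[0, 1\]).
#' @export
predictive_values_at_cutoffs <- function(units,
                                         cutoffs = c(20, 25, 43.6, 44.1)) {
  if (!is.data.frame(units) || nrow(units) == 0L)
    stop("'units' must be a non-empty data.frame")
  rows <- lapply(cutoffs, function(cut) {
    cc <- confusion_counts(classify_by_cutoff(units$dose, cut), units$event)
    total <- cc$tp + cc$fp + cc$tn + cc$fn
    prev <- (cc$tp + cc$fn) / total
    sens <- if (cc$tp + cc$fn > 0) cc$tp / (cc$tp + cc$fn) else NA_real_
    spec <- if (cc$tn + cc$fp > 0) cc$tn / (cc$tn + cc$fp) else NA_real_
    # when one outcome class is absent its rate does not enter the Eq. 4/5
    # formulas (multiplied by prev or 1-prev = 0); substitute 0 so the
    # formula value still equals the count ratio where that is defined
    sens0 <- if (is.na(sens)) 0 else sens
    spec0 <- if (is.na(spec)) 0 else spec
    ppv_val <- if (cc$tp + cc$fp > 0)
      suppressWarnings(ppv(sens0, spec0, prev)) else NA_real_
    npv_val <- if (cc$tn + cc$fn > 0)
      suppressWarnings(npv(sens0, spec0, prev)) else NA_real_
    data.frame(cutoff_gy = cut, tp = cc$tp, fp = cc$fp, tn = cc$tn,
               fn = cc$fn, sensitivity = sens, specificity = spec,
               prevalence = prev, ppv = ppv_val, npv = npv_val)
  })
  do.call(rbind, rows)
}
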