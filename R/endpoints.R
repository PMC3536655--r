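#' Salivary flow ratio relative to baseline
#'
#' Follow-up salivary excretion factor (SEF) as a fraction of the
#' pre-treatment value; the quantity graded by the LENT-SOMA salivary-flow
#' bands.
#'
#' @param baseline Pre-treatment SEF (percent), > 0; vectorized.
#' @param followup Follow-up SEF (percent), >= 0.
#' @return Dimensionless ratio followup/baseline.
#' @export
flow_ratio <- function(baseline, followup) {
  if (any(!is.finite(baseline)) || any(baseline <= 0))
    stop("'baseline' must be positive")
  if (any(is.finite(followup) & followup < 0))
    stop("'followup' must be non-negative")
  followup / baseline
}

#' LENT-SOMA xerostomia grade from a salivary flow ratio
#'
#' Grading bands on residual flow as a fraction of baseline: grade 4 for
#' 0-25%, grade 3 for 26-50%, grade 2 for 51-75%, grade 1 for 76-95%, grade 0
#' above 95%. Boundary values are assigned to the more severe grade (the
#' bands are read as ratio <= upper bound), a single conservative convention.
#'
#' @param ratio Flow ratio(s) >= 0, from [flow_ratio()].
#' @return Integer grade(s) in 0..4. `grade >= 3` is the grade-3+ criterion.
#' @examples
#' lentsoma_grade(c(0.25, 0.40, 1.2))  # 4, 3, 0
#' @export
lentsoma_grade <- function(ratio) {
  if (any(!is.finite(ratio)) || any(ratio < 0))
    stop("'ratio' must be non-negative")
  ifelse(ratio <= 0.25, 4L,
    ifelse(ratio <= 0.50, 3L,
      ifelse(ratio <= 0.75, 2L,
        ifelse(ratio <= 0.95, 1L, 0L))))
}

#' Binary SEF complication endpoint
#'
#' The primary scintigraphic endpoint: salivary flow at or below 45% of the
#' pre-treatment value (inclusive). Note this is deliberately stricter than
#' the 50% upper edge of the LENT-SOMA grade-3 band; both predicates are
#' exposed ([lentsoma_grade()] gives the band).
#'
#' @param ratio Flow ratio(s) >= 0.
#' @return Logical event indicator(s).
#' @examples
#' sef_event(c(0.45, 0.46))  # TRUE, FALSE
#' @export
sef_event <- function(ratio) {
  if (any(!is.finite(ratio)) || any(ratio < 0))
    stop("'ratio' must be non-negative")
  ratio <= 0.45
}

#' Binary quality-of-life xerostomia endpoint
#'
#' Binarizes the 4-level xerostomia item (1 = not at all, 2 = a little,
#' 3 = quite a bit, 4 = very much) at moderate-to-severe, i.e. score >= 3.
#'
#' @param score Integer score(s) in 1..4.
#' @return Logical event indicator(s).
#' @export
qol_event <- function(score) {
  if (any(!is.finite(score)) || any(score != round(score)) ||
      any(score < 1) || any(score > 4))
    stop("'score' must be an integer in 1..4")
  score >= 3
}
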