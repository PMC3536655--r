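#' Lyman-Kutcher-Burman model parameters
#'
#' The LKB model has three parameters: the volume-effect exponent `n`
#' (applied when reducing a DVH to EUD), the slope parameter `m` (smaller m,
#' steeper dose-response), and `td50`, the uniform dose giving a 50%
#' complication probability.
#'
#' `m` is floored at 1e-4 to keep the dose-response curve away from a
#' degenerate step function.
#'
#' @param td50 Dose in Gy at 50% complication probability; > 0.
#' @param m Slope parameter, dimensionless; > 0.
#' @param n Volume-effect exponent; > 0. Defaults to 1 (mean-dose model,
#'   appropriate for a parallel organ such as the parotid gland).
#' @return An object of class `lkb_params`.
#' @examples
#' lkb_params(td50 = 43.6, m = 0.18)
#' @export
lkb_params <- function(td50, m, n = 1) {
  for (nm in c("td50", "m", "n")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive number", nm))
  }
  if (m < 1e-4) {
    warning("'m' below 1e-4; floored to avoid a degenerate step response")
    m <- 1e-4
  }
  structure(list(n = n, m = m, td50 = td50), class = "lkb_params")
}

#' @export
print.lkb_params <- function(x, ...) {
  cat(sprintf("LKB parameters: TD50 = %.4g Gy, m = %.4g, n = %.4g\n",
              x$td50, x$m, x$n))
  invisible(x)
}

#' Standardized dose deviate of the LKB model
#'
#' `t = (EUD - TD50) / (m * TD50)`, the probit argument of the LKB
#' dose-response.
#'
#' @param eud EUD (or mean dose when n = 1) in Gy; vectorized.
#' @param params An `lkb_params` object.
#' @return Dimensionless deviate(s).
#' @export
lkb_t <- function(eud, params) {
  if (!inherits(params, "lkb_params")) stop("'params' must be lkb_params")
  (eud - params$td50) / (params$m * params$td50)
}

#' Normal tissue complication probability
#'
#' LKB probit dose-response: the standard-normal CDF of [lkb_t()]. Evaluated
#' with the erf-based CDF (`stats::pnorm`), accurate to well below 1e-12,
#' rather than by literal quadrature of the probit integral.
#'
#' @inheritParams lkb_t
#' @return Complication probability in \[0, 1\]; vectorized over `eud`.
#' @examples
#' p <- lkb_params(td50 = 43.6, m = 0.18)
#' ntcp(43.6, p)  # 0.5 by definition of TD50
#' ntcp(c(20, 25), p)
#' @export
ntcp <- function(eud, params) {
  stats::pnorm(lkb_t(eud, params))
}

#' Dose at a given complication probability
#'
#' Inverse of [ntcp()]: the unique EUD with `ntcp(eud, params) = p`,
#' `td50 * (1 + m * qnorm(p))`.
#'
#' @param p Probability strictly inside (0, 1); vectorized.
#' @param params An `lkb_params` object.
#' @return EUD in Gy.
#' @export
inverse_ntcp <- function(p, params) {
  if (!inherits(params, "lkb_params")) stop("'params' must be lkb_params")
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("'p' must lie strictly inside (0, 1)")
  params$td50 * (1 + params$m * stats::qnorm(p))
}

#' Tabulate an NTCP dose-response curve
#'
#' Convenience grid evaluation for plotting or export.
#'
#' @param params An `lkb_params` object.
#' @param dose Numeric vector of doses (Gy); default a 0-80 Gy grid.
#' @return A data.frame with columns `dose_gy` and `ntcp`.
#' @export
ntcp_curve <- function(params, dose = seq(0, 80, by = 0.5)) {
  data.frame(dose_gy = dose, ntcp = ntcp(dose, params))
}
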