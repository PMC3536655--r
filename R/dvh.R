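#' Construct a dose-volume histogram curve
#'
#' A DVH curve is an ordered set of (dose, volume) pairs describing how an
#' organ's volume is distributed over dose. Differential curves give the
#' volume fraction in each dose bin (fractions sum to 1); cumulative curves
#' give the fraction receiving at least each dose (start at 1,
#' non-increasing).
#'
#' Volume columns supplied in percent (values above 1.5 totalling about 100)
#' are rescaled to fractions with a message.
#'
#' @param dose Numeric vector of bin doses in Gy, strictly increasing, all
#'   non-negative.
#' @param volume Numeric vector of volume fractions, same length as `dose`.
#' @param form `"differential"` or `"cumulative"`.
#' @param gland_id Optional identifier carried along with the curve.
#' @return An object of class `dvh_curve`: a list with elements `gland_id`,
#'   `dose`, `volume` and `form`.
#' @examples
#' dvh_curve(c(10, 30), c(0.5, 0.5))
#' @export
dvh_curve <- function(dose, volume, form = c("differential", "cumulative"),
                      gland_id = NA_character_) {
  form <- match.arg(form)
  if (!is.numeric(dose) || !is.numeric(volume))
    stop("'dose' and 'volume' must be numeric")
  if (length(dose) != length(volume))
    stop("'dose' and 'volume' must have the same length")
  if (length(dose) == 0L) stop("empty DVH curve")
  if (any(!is.finite(dose)) || any(!is.finite(volume)))
    stop("non-finite values in DVH curve")
  if (any(dose < 0)) stop("doses must be non-negative")
  if (is.unsorted(dose, strictly = TRUE))
    stop("doses must be strictly increasing")
  if (any(volume < 0)) stop("volume fractions must be non-negative")

  if (any(volume > 1.5)) {
    total <- if (form == "differential") sum(volume) else volume[1L]
    if (abs(total - 100) < 1) {
      message("volume column looks like percentages; rescaling to fractions")
      volume <- volume / 100
    } else {
      stop("volume values out of range: neither fractions nor percentages")
    }
  }

  if (form == "differential") {
    if (abs(sum(volume) - 1) > 1e-9)
      stop("differential volume fractions must sum to 1")
  } else {
    if (is.unsorted(rev(volume)))
      stop("cumulative volume fractions must be non-increasing")
    if (abs(volume[1L] - 1) > 1e-9)
      stop("cumulative curve must start at volume fraction 1")
  }

  structure(
    list(gland_id = gland_id, dose = as.numeric(dose),
         volume = as.numeric(volume), form = form),
    class = "dvh_curve"
  )
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("DVH curve (%s), %d bins, dose %.4g-%.4g Gy\n",
              x$form, length(x$dose), min(x$dose), max(x$dose)))
  invisible(x)
}

#' Convert a DVH curve to differential form
#'
#' Cumulative curves are differenced with a right-edge convention: the volume
#' lost between consecutive cumulative points is assigned to the higher dose
#' of the pair, and any residual cumulative volume at the last tabulated dose
#' stays at that dose. Zero-mass bins are dropped. Differential input is
#' returned unchanged.
#'
#' @param curve A `dvh_curve`.
#' @return A `dvh_curve` in differential form.
#' @export
as_differential <- function(curve) {
  if (!inherits(curve, "dvh_curve")) stop("'curve' must be a dvh_curve")
  if (curve$form == "differential") return(curve)
  d <- curve$dose
  cv <- curve$volume
  k <- length(d)
  v <- numeric(k)
  v[1L] <- 1 - cv[1L]                 # ~0 by the start-at-1 invariant
  if (k > 1L) v[2:k] <- cv[1:(k - 1L)] - cv[2:k]
  v[k] <- v[k] + cv[k]                # volume at or above the last dose
  keep <- v > 0
  dvh_curve(d[keep], v[keep], form = "differential", gland_id = curve$gland_id)
}

#' Equivalent uniform dose of a DVH curve
#'
#' The EUD is the generalized (power) mean of the differential DVH,
#' `(sum_i v_i * D_i^(1/n))^n`, the uniform dose with the same modelled
#' effect as the heterogeneous distribution. With `n = 1` it equals the
#' volume-weighted mean dose. Cumulative input is converted first.
#'
#' @param curve A `dvh_curve`.
#' @param n Volume-effect exponent, a single number > 0. Values near 0
#'   emphasise the maximum dose (serial organs); `n = 1` gives the mean dose
#'   (parallel organs such as the parotid).
#' @return EUD in Gy.
#' @examples
#' eud(dvh_curve(c(10, 30), c(0.5, 0.5)), n = 0.5)  # 22.36 Gy
#' @export
eud <- function(curve, n) {
  if (!inherits(curve, "dvh_curve")) stop("'curve' must be a dvh_curve")
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n <= 0)
    stop("'n' must be a single positive number")
  curve <- as_differential(curve)
  sum(curve$volume * curve$dose^(1 / n))^n
}

#' Mean dose of a DVH curve
#'
#' Volume-weighted mean dose, identical to `eud(curve, n = 1)`.
#'
#' @param curve A `dvh_curve`.
#' @return Mean dose in Gy.
#' @export
mean_dose <- function(curve) {
  if (!inherits(curve, "dvh_curve")) stop("'curve' must be a dvh_curve")
  curve <- as_differential(curve)
  sum(curve$volume * curve$dose)
}

#' Read a DVH curve from a delimited text file
#'
#' Expects two columns (dose in Gy, volume fraction or percent), comma- or
#' whitespace-delimited, with an optional header row.
#'
#' @param path Path to the file.
#' @param form Form of the stored curve, `"differential"` or `"cumulative"`.
#' @param gland_id Optional identifier for the curve.
#' @return A validated `dvh_curve` (in its stored form; use
#'   [as_differential()] to difference a cumulative curve).
#' @export
read_dvh <- function(path, form = c("differential", "cumulative"),
                     gland_id = NA_character_) {
  form <- match.arg(form)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("malformed DVH file: empty")
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  fields <- strsplit(trimws(first), if (sep == ",") "," else "[[:space:]]+")[[1]]
  header <- any(is.na(suppressWarnings(as.numeric(fields))))
  df <- utils::read.table(path, sep = sep, header = header,
                          strip.white = TRUE)
  if (ncol(df) < 2L) stop("malformed DVH file: need two columns (dose, volume)")
  dvh_curve(df[[1]], df[[2]], form = form, gland_id = gland_id)
}
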