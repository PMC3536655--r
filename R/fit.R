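#' Negative log-likelihood of binary complication data under the LKB model
#'
#' Bernoulli likelihood of observed events given LKB-modelled complication
#' probabilities: `-sum(y*log(p) + (1-y)*log(1-p))` with
#' `p = ntcp(dose, params)` clamped to `[1e-12, 1 - 1e-12]` for numerical
#' safety.
#'
#' @param params An `lkb_params` object.
#' @param units A data.frame with columns `dose` (EUD or mean dose, Gy) and
#'   `event` (logical or 0/1).
#' @return A single non-negative number.
#' @export
neg_loglik <- function(params, units) {
  if (!inherits(params, "lkb_params")) stop("'params' must be lkb_params")
  if (!is.data.frame(units) || nrow(units) == 0L)
    stop("'units' must be a non-empty data.frame with dose and event")
  p <- ntcp(units$dose, params)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  y <- as.numeric(units$event)
  -sum(y * log(p) + (1 - y) * log1p(-p))
}

# log-likelihood of the intercept-only (constant-probability) model
.loglik_null <- function(event) {
  y <- as.numeric(event)
  phat <- mean(y)
  sum(y * log(phat) + (1 - y) * log1p(-phat))
}

# fixed multi-start grid: geometric 20/50/80% quantiles of each box
.start_grid <- function(bounds) {
  q <- c(0.2, 0.5, 0.8)
  gq <- function(b) exp(log(b[1]) + q * (log(b[2]) - log(b[1])))
  expand.grid(td50 = gq(bounds$td50), m = gq(bounds$m))
}

#' Maximum-likelihood fit of the LKB model to binary dose-response data
#'
#' Minimizes [neg_loglik()] over `(td50, m)` on log-transformed coordinates
#' within box bounds, starting from a fixed 3x3 grid of initial values (plus
#' `init` if given) and keeping the best optimum, so the fit is deterministic
#' for a given input. The volume exponent `n` is fixed (default 1, the
#' mean-dose model); an experimental free-`n` fit over per-gland DVH curves
#' is available via `curves`.
#'
#' Profile-likelihood 95% confidence intervals for `td50` and `m` are
#' attached unless `compute_ci = FALSE` (see [profile_ci()]).
#'
#' @param units A data.frame with columns `dose` (Gy) and `event`
#'   (logical/0-1), containing at least one event and one non-event at more
#'   than one dose level.
#' @param fix_n Value at which the volume exponent is fixed (default 1).
#' @param init Optional named numeric `c(td50 = , m = )` additional start.
#' @param bounds List with elements `td50` and `m`, each `c(lower, upper)`
#'   box bounds; defaults `td50` in \[5, 100\] Gy and `m` in \[0.01, 1\].
#' @param compute_ci Logical; attach profile CIs (default TRUE).
#' @param level Confidence level for the intervals.
#' @param curves Optional list of `dvh_curve` objects (one per unit). When
#'   supplied with `fix_n = NULL`, `n` is estimated too (experimental) and
#'   doses are recomputed as `eud(curve, n)` inside the likelihood.
#' @return An object of class `lkb_fit`: estimates, log-likelihoods, sample
#'   size, confidence intervals, convergence and boundary flags, and an
#'   optimizer trace summary in `fit_meta`.
#' @examples
#' set.seed(1)
#' d <- runif(400, 10, 70)
#' y <- rbinom(400, 1, ntcp(d, lkb_params(td50 = 43.6, m = 0.18)))
#' fit_lkb(data.frame(dose = d, event = y), compute_ci = FALSE)
#' @export
fit_lkb <- function(units, fix_n = 1, init = NULL,
                    bounds = list(td50 = c(5, 100), m = c(0.01, 1)),
                    compute_ci = TRUE, level = 0.95, curves = NULL) {
  if (!is.data.frame(units) && is.null(curves))
    stop("'units' must be a data.frame with dose and event")
  free_n <- is.null(fix_n)
  if (free_n && is.null(curves))
    stop("a free-n fit requires per-unit DVH 'curves'")

  if (!is.null(curves)) {
    if (!all(vapply(curves, inherits, logical(1), "dvh_curve")))
      stop("'curves' must be a list of dvh_curve objects")
    event <- as.logical(units$event)
  } else {
    event <- as.logical(units$event)
  }
  y <- as.numeric(event)
  if (length(y) < 2L) stop("need at least two observations")
  if (all(y == 1) || all(y == 0))
    stop("all outcomes are of a single class: LKB parameters are not identifiable")
  if (is.null(curves) && length(unique(units$dose)) == 1L)
    stop("all observations share one dose level: td50 is not identifiable")

  nll_at <- function(td50, m, n) {
    dose <- if (!is.null(curves) && free_n)
      vapply(curves, eud, numeric(1), n = n) else units$dose
    p <- stats::pnorm((dose - td50) / (m * td50))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(y * log(p) + (1 - y) * log1p(-p))
  }

  if (free_n) {
    warning("free-n LKB fitting is experimental")
    n_box <- c(0.05, 5)
    obj <- function(th) nll_at(exp(th[1]), exp(th[2]), exp(th[3]))
    lower <- log(c(bounds$td50[1], bounds$m[1], n_box[1]))
    upper <- log(c(bounds$td50[2], bounds$m[2], n_box[2]))
    starts <- .start_grid(bounds)
    starts$n <- 1
  } else {
    obj <- function(th) nll_at(exp(th[1]), exp(th[2]), fix_n)
    lower <- log(c(bounds$td50[1], bounds$m[1]))
    upper <- log(c(bounds$td50[2], bounds$m[2]))
    starts <- .start_grid(bounds)
  }
  if (!is.null(init))
    starts <- rbind(starts, data.frame(td50 = init[["td50"]], m = init[["m"]],
                                       n = if (free_n) 1 else NULL))

  fits <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    th0 <- log(as.numeric(starts[i, ]))
    fits[[i]] <- tryCatch(
      stats::optim(th0, obj, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 1000, factr = 1e3)),
      error = function(e) NULL
    )
  }
  trace <- lapply(fits, function(res)
    if (is.null(res)) list(value = NA_real_, convergence = NA)
    else list(value = res$value, convergence = res$convergence))
  vals <- vapply(trace, `[[`, numeric(1), "value")
  if (all(is.na(vals))) stop("LKB fit failed from every start")
  # among starts tying the best value, prefer one with a clean optimizer exit
  near <- which(!is.na(vals) & vals <= min(vals, na.rm = TRUE) + 1e-8)
  conv0 <- near[vapply(near, function(i) trace[[i]]$convergence == 0,
                       logical(1))]
  ibest <- if (length(conv0) > 0) conv0[which.min(vals[conv0])]
           else near[which.min(vals[near])]
  best <- c(fits[[ibest]], list(start = ibest))

  est <- exp(best$par)
  td50_hat <- est[1]
  m_hat <- est[2]
  n_hat <- if (free_n) est[3] else fix_n

  boundary <- m_hat <= bounds$m[1] * 1.05
  if (boundary)
    warning("slope m estimated at its lower bound; outcomes may be ",
            "perfectly separated by dose (td50/m not jointly identifiable)")

  fit <- structure(list(
    params = lkb_params(td50 = td50_hat, m = m_hat, n = n_hat),
    loglik = -best$value,
    loglik_null = .loglik_null(y),
    n_obs = length(y),
    n_events = sum(y),
    ci = NULL,
    level = level,
    converged = identical(best$convergence, 0L) || best$convergence == 0,
    boundary = boundary,
    free_n = free_n,
    bounds = bounds,
    fit_meta = list(starts = starts, best_start = best$start,
                    optim_counts = best$counts, trace = trace)
  ), class = "lkb_fit")

  if (compute_ci && !free_n && !boundary) {
    un <- data.frame(dose = units$dose, event = y)
    fit$ci <- list(
      td50 = profile_ci(fit, un, "td50", level = level),
      m = profile_ci(fit, un, "m", level = level),
      level = level
    )
  }
  fit
}

#' @export
print.lkb_fit <- function(x, ...) {
  cat("LKB NTCP maximum-likelihood fit\n")
  cat(sprintf("  n_obs = %d (%d events), n fixed at %.3g%s\n",
              x$n_obs, x$n_events, x$params$n,
              if (x$free_n) " [free-n, experimental]" else ""))
  cat(sprintf("  TD50 = %.3f Gy, m = %.4f\n", x$params$td50, x$params$m))
  if (!is.null(x$ci)) {
    cat(sprintf("  %.0f%% profile CI: TD50 [%.2f, %.2f] Gy, m [%.4f, %.4f]\n",
                100 * x$ci$level, x$ci$td50[1], x$ci$td50[2],
                x$ci$m[1], x$ci$m[2]))
  }
  cat(sprintf("  logLik = %.4f (null %.4f), converged: %s%s\n",
              x$loglik, x$loglik_null, x$converged,
              if (x$boundary) ", boundary" else ""))
  invisible(x)
}

#' Profile-likelihood confidence interval for an LKB parameter
#'
#' Bounds are the parameter values where twice the drop from the maximized
#' log-likelihood to the profile log-likelihood (the other parameter
#' re-maximized) equals the chi-squared(1) quantile at `level`
#' (3.841 at 95%). Each bound is located by bisection to a relative
#' tolerance of 1e-4 of the estimate. A bound that runs into the search box
#' is returned at the box edge and flagged open in the `"open"` attribute.
#'
#' @param fit A converged `lkb_fit` (fixed-n).
#' @param units The (dose, event) data the fit used.
#' @param param `"td50"` or `"m"`.
#' @param level Confidence level in (0, 1).
#' @return Named numeric `c(lower, upper)` with attribute `open`, a logical
#'   pair flagging open-ended bounds.
#' @export
profile_ci <- function(fit, units, param = c("td50", "m"), level = 0.95) {
  if (!inherits(fit, "lkb_fit")) stop("'fit' must be an lkb_fit")
  if (!fit$converged) stop("profile CI requires a converged fit")
  if (fit$free_n) stop("profile CIs are implemented for fixed-n fits only")
  param <- match.arg(param)
  if (level <= 0 || level >= 1) stop("'level' must be in (0, 1)")
  thr <- stats::qchisq(level, df = 1)
  y <- as.numeric(units$event)
  dose <- units$dose
  n_fix <- fit$params$n

  nll2 <- function(td50, m) {
    p <- stats::pnorm((dose - td50) / (m * td50))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(y * log(p) + (1 - y) * log1p(-p))
  }
  box <- fit$bounds[[param]]
  other_box <- fit$bounds[[setdiff(c("td50", "m"), param)]]
  prof_nll <- function(x) {
    f <- if (param == "td50") function(lo) nll2(x, exp(lo))
         else function(lo) nll2(exp(lo), x)
    stats::optimize(f, interval = log(other_box), tol = 1e-7)$objective
  }
  nll_min <- -fit$loglik
  est <- fit$params[[param]]
  dev <- function(x) 2 * (prof_nll(x) - nll_min)

  bisect <- function(a, b) {
    # dev(a) >= thr > dev(b); shrink until |b - a| small
    tol <- 1e-4 * est
    while (abs(b - a) > tol) {
      mid <- (a + b) / 2
      if (dev(mid) >= thr) a <- mid else b <- mid
    }
    (a + b) / 2
  }

  open <- c(lower = FALSE, upper = FALSE)
  if (dev(box[1]) < thr) {
    lower <- box[1]; open["lower"] <- TRUE
  } else {
    lower <- bisect(box[1], est)
  }
  if (dev(box[2]) < thr) {
    upper <- box[2]; open["upper"] <- TRUE
  } else {
    upper <- bisect(box[2], est)
  }
  out <- c(lower = min(lower, est), upper = max(upper, est))
  attr(out, "open") <- open
  out
}
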