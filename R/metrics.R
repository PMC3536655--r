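#' Nagelkerke's pseudo R-squared
#'
#' Likelihood-ratio R-squared for binary-outcome models, normalized so a
#' saturated model reaches 1:
#' `[1 - exp(2*(ll0 - ll1)/n)] / [1 - exp(2*ll0/n)]`.
#'
#' @param loglik_model Log-likelihood of the fitted model.
#' @param loglik_null Log-likelihood of the intercept-only model; must not
#'   exceed `loglik_model`.
#' @param n_obs Number of observations.
#' @return A value in \[0, 1\].
#' @export
nagelkerke_r2 <- function(loglik_model, loglik_null, n_obs) {
  if (n_obs < 1) stop("'n_obs' must be >= 1")
  if (loglik_model < loglik_null - 1e-9)
    stop("'loglik_model' must be at least 'loglik_null'")
  denom <- 1 - exp(2 * loglik_null / n_obs)
  if (denom <= 0)
    stop("null model is saturated (all outcomes identical); R2 undefined")
  (1 - exp(2 * (loglik_null - loglik_model) / n_obs)) / denom
}

#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' `(concordant pairs + 0.5 * tied pairs) / (n1 * n0)` over all
#' positive-negative pairs, computed via average ranks.
#'
#' @param scores Numeric predicted scores or probabilities.
#' @param labels Logical (or 0/1) outcome labels; both classes required.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both outcome classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Hosmer-Lemeshow calibration test
#'
#' Observations are sorted by predicted probability and split into `groups`
#' near-equal risk groups (tied predictions stay together in the lower
#' group). The statistic sums `(O - E)^2 / E` over events and non-events in
#' each group; under good calibration it is approximately chi-squared with
#' `groups - 2` degrees of freedom. Groups whose expected event or non-event
#' count is zero are merged with the neighbouring group (with a warning),
#' reducing the degrees of freedom.
#'
#' @param pred Predicted event probabilities.
#' @param labels Logical (or 0/1) observed outcomes.
#' @param groups Number of risk groups (default 10, conventional deciles);
#'   requires at least `2 * groups` observations.
#' @return A list with `chi2`, `df`, `p` and `groups_used`.
#' @export
hosmer_lemeshow <- function(pred, labels, groups = 10) {
  n <- length(pred)
  if (length(labels) != n) stop("length mismatch")
  if (n < 2 * groups)
    stop("need at least 2*groups observations for the Hosmer-Lemeshow test")
  ord <- order(pred)
  p <- pred[ord]
  y <- as.numeric(labels[ord])
  g <- floor((seq_len(n) - 1) * groups / n) + 1L
  # keep tied predictions together in the lower group
  g <- g[match(p, p)]

  agg <- function(g) {
    ids <- sort(unique(g))
    list(
      o1 = vapply(ids, function(i) sum(y[g == i]), numeric(1)),
      e1 = vapply(ids, function(i) sum(p[g == i]), numeric(1)),
      n_g = vapply(ids, function(i) sum(g == i), numeric(1)),
      ids = ids
    )
  }
  a <- agg(g)
  merged <- FALSE
  while (length(a$ids) > 3L &&
         any(a$e1 <= 0 | (a$n_g - a$e1) <= 0)) {
    bad <- which(a$e1 <= 0 | (a$n_g - a$e1) <= 0)[1L]
    neighbour <- if (bad == 1L) a$ids[2L] else a$ids[bad - 1L]
    g[g == a$ids[bad]] <- neighbour
    a <- agg(g)
    merged <- TRUE
  }
  if (merged)
    warning("risk groups with zero expected counts merged with a neighbour; ",
            "degrees of freedom reduced")

  o1 <- a$o1
  e1 <- a$e1
  o0 <- a$n_g - o1
  e0 <- a$n_g - e1
  chi2 <- sum((o1 - e1)^2 / e1 + (o0 - e0)^2 / e0)
  df <- length(a$ids) - 2L
  if (df < 1L) stop("fewer than 3 usable risk groups; test undefined")
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE),
       groups_used = length(a$ids))
}

#' Pearson chi-squared test of a 2x2 table
#'
#' Uncorrected (no Yates continuity correction) Pearson chi-squared with
#' expected counts from the margins; 1 degree of freedom.
#'
#' @param table A 2x2 matrix of non-negative counts with all margins > 0.
#' @return A list with `chi2`, `df` and `p`.
#' @export
pearson_chi2_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("'table' must be 2x2")
  if (any(table < 0) || any(table != round(table)))
    stop("'table' must hold non-negative integer counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero margin in 2x2 table; chi-squared undefined")
  res <- stats::chisq.test(table, correct = FALSE)
  list(chi2 = unname(res$statistic), df = 1L, p = res$p.value)
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' Pearson correlation of average-ranked data; the p-value uses the
#' t-approximation `t = rho * sqrt((n-2)/(1-rho^2))` with `n - 2` degrees of
#' freedom (two-sided).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A list with `rho` and `p`.
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("length mismatch")
  if (n < 3L) stop("need at least 3 paired observations")
  if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0)
    stop("zero rank variance: correlation undefined")
  rho <- stats::cor(x, y, method = "spearman")
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p)
}
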