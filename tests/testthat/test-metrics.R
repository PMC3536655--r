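test_that("nagelkerke_r2 matches hand-evaluated values and its range", {
  expect_equal(nagelkerke_r2(-5, -5, 20), 0)
  # perfect fit normalizes to 1 for any null
  expect_equal(nagelkerke_r2(0, 10 * log(0.5), 10), 1)
  # direct arithmetic oracle: n=10, ll0 = 10*log(0.5), ll1 = -5
  ll0 <- 10 * log(0.5)
  byhand <- (1 - exp(2 * (ll0 - (-5)) / 10)) / (1 - exp(2 * ll0 / 10))
  expect_equal(nagelkerke_r2(-5, ll0, 10), byhand)
  expect_error(nagelkerke_r2(-6, -5, 10), "at least")
  expect_error(nagelkerke_r2(0, 0, 10), "saturated")
})

test_that("nagelkerke_r2 stays in [0, 1] on random nested fits", {
  set.seed(14)
  for (i in 1:200) {
    n <- sample(10:200, 1)
    ll0 <- -runif(1, 0.1, 0.6) * n
    ll1 <- ll0 + runif(1, 0, -ll0)
    r2 <- nagelkerke_r2(ll1, ll0, n)
    expect_gte(r2, 0)
    expect_lte(r2, 1)
  }
})

test_that("auc handles separation, ties, and matches the pairwise oracle", {
  expect_equal(auc(c(1, 2, 3, 10, 11), c(F, F, F, T, T)), 1)
  expect_equal(auc(rep(0.4, 8), rep(c(TRUE, FALSE), 4)), 0.5)
  # six scores with one tied pair, enumerated by hand via the oracle
  s <- c(0.1, 0.4, 0.4, 0.6, 0.7, 0.9)
  l <- c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE)
  expect_equal(auc(s, l), auc_bruteforce(s, l))
  expect_error(auc(1:4, rep(TRUE, 4)), "both outcome classes")

  set.seed(21)
  for (i in 1:60) {
    n <- sample(4:50, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # force ties
    labels <- runif(n) < 0.5
    if (all(labels) || !any(labels)) labels[1:2] <- c(TRUE, FALSE)
    expect_identical(auc(scores, labels), auc_bruteforce(scores, labels))
  }
})

test_that("hosmer_lemeshow is zero for exactly calibrated bins, df = groups-2", {
  # 10 groups of 20 whose predictions equal the bin event rates
  pred <- rep(seq(0.05, 0.95, by = 0.1), each = 20)
  labels <- unlist(lapply(seq(1, 19, by = 2), function(k)
    rep(c(TRUE, FALSE), c(k, 20 - k))))
  hl <- hosmer_lemeshow(pred, labels, groups = 10)
  expect_equal(hl$chi2, 0)
  expect_equal(hl$df, 8)
  expect_equal(hl$p, 1)
  expect_error(hosmer_lemeshow(runif(15), runif(15) < 0.5, groups = 10),
               "at least")
})

test_that("hosmer_lemeshow p is near-uniform under a calibrated null", {
  # the groups-2 degrees of freedom presume the model's parameters were
  # estimated from the same data, so the null refits a correctly specified
  # logistic model in every replicate
  set.seed(500)
  pvals <- replicate(500, {
    x <- runif(100, -2, 2)
    labels <- runif(100) < plogis(-0.5 + 1.2 * x)
    pred <- fitted(glm(labels ~ x, family = binomial))
    hosmer_lemeshow(pred, labels)$p
  })
  expect_gt(mean(pvals), 0.4)
  expect_lt(mean(pvals), 0.6)
})

test_that("groups with zero expected counts are merged with a warning", {
  pred <- c(rep(0, 30), runif(70, 0.2, 0.8))
  set.seed(9)
  labels <- runif(100) < pred
  expect_warning(hl <- hosmer_lemeshow(pred, labels), "merged")
  expect_lt(hl$groups_used, 10)
  expect_equal(hl$df, hl$groups_used - 2)
})

test_that("pearson 2x2 chi-squared is uncorrected and symmetric", {
  even <- matrix(c(10, 10, 10, 10), 2)
  r <- pearson_chi2_2x2(even)
  expect_equal(r$chi2, 0)
  expect_equal(r$p, 1)

  tab <- matrix(c(20, 5, 5, 20), 2)
  expect_equal(pearson_chi2_2x2(tab)$chi2, 18)    # sum (O-E)^2/E by hand
  expect_equal(pearson_chi2_2x2(t(tab))$chi2, pearson_chi2_2x2(tab)$chi2)
  expect_error(pearson_chi2_2x2(matrix(c(0, 0, 3, 4), 2)), "margin")
})

test_that("spearman_cor matches the rank definition and base R", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearman_cor(x, x * 2 + 1)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)
  set.seed(33)
  for (i in 1:30) {
    n <- sample(3:8, 1)
    a <- runif(n); b <- runif(n)
    got <- spearman_cor(a, b)
    expect_equal(got$rho, cor(rank(a), rank(b)))   # definition, by ranks
    tstat <- got$rho * sqrt((n - 2) / (1 - got$rho^2))
    expect_equal(got$p, 2 * pt(-abs(tstat), n - 2))
  }
  expect_error(spearman_cor(rep(1, 5), 1:5), "rank variance")
})
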