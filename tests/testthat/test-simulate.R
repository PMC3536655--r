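test_that("cohort_config validates its blocks", {
  expect_s3_class(cohort_config(), "cohort_config")
  expect_error(cohort_config(n_patients = 0), ">= 1")
  expect_error(cohort_config(ipsi_dose = list(mean = 50, sd = 0,
                                              range = c(20, 80))), "> 0")
  expect_error(cohort_config(ipsi_dose = list(mean = 90, sd = 10,
                                              range = c(20, 80))),
               "contain its mean")
  expect_error(
    cohort_config(contra_dose = list(mean = 36.7, sd = 0.1,
                                     range = c(36.69, 57.6))),
    NA)  # narrow but feasible truncation is accepted
  expect_error(cohort_config(dose_correlation = 1), "\\(-1, 1\\)")
})

test_that("simulate_cohort is reproducible and has the study's shape", {
  cfg <- cohort_config(seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)                      # bit-for-bit from the seed
  expect_equal(nrow(a), 62)
  expect_equal(length(unique(a$patient_id)), 31)
  expect_equal(sum(a$laterality == "ipsilateral"), 31)

  ipsi <- a$mean_dose_gy[a$laterality == "ipsilateral"]
  contra <- a$mean_dose_gy[a$laterality == "contralateral"]
  expect_true(all(ipsi >= 26.9 & ipsi <= 74.8))
  expect_true(all(contra >= 7.6 & contra <= 57.6))
  expect_true(all(a$baseline_sef >= 19.2 & a$baseline_sef <= 72.8))
})

test_that("dose marginals converge to the configured means", {
  cfg <- cohort_config(n_patients = 500, seed = 123)
  co <- simulate_cohort(cfg)
  ipsi <- co$mean_dose_gy[co$laterality == "ipsilateral"]
  contra <- co$mean_dose_gy[co$laterality == "contralateral"]
  expect_lt(abs(mean(ipsi) - 51.7), 3)
  expect_lt(abs(mean(contra) - 36.7), 3)
  expect_lt(abs(mean(co$baseline_sef) - 48.1), 3)
})

test_that("derived endpoints reproduce the injected event flags", {
  cfg <- cohort_config(n_patients = 100, seed = 55)
  co <- simulate_cohort(cfg)
  truth <- attr(co, "sim_truth")
  expect_identical(co$event_sef, truth$event_sef)
  pat_first <- !duplicated(co$patient_id)
  expect_identical(co$event_qol[pat_first], truth$event_qol)
  # QoL events sit at the spared-gland dose response
  expect_identical(qol_event(co$qol_score), co$event_qol)
})

test_that("near-step responses separate events almost perfectly by td50", {
  cfg <- cohort_config(n_patients = 300, seed = 9,
                       true_params_sef = lkb_params(td50 = 43.6, m = 0.01))
  co <- simulate_cohort(cfg)
  margin <- 0.05 * 43.6   # 5 sigma of the steep response
  high <- co$event_sef[co$mean_dose_gy > 43.6 + margin]
  low <- co$event_sef[co$mean_dose_gy < 43.6 - margin]
  expect_true(all(high))
  expect_false(any(low))
})

test_that("event prevalence is self-consistent with the dose-response truth", {
  # per-gland SEF prevalence must track the mean NTCP over the cohort's own
  # gland doses (binomial noise only): a generative-bug canary
  for (s in 1:5) {
    co <- simulate_cohort(cohort_config(n_patients = 400, seed = s))
    u <- analysis_units(co, "sef")
    implied <- mean(ntcp(u$dose, lkb_params(td50 = 43.6, m = 0.18)))
    se <- sqrt(implied * (1 - implied) / nrow(u))
    expect_lt(abs(mean(u$event) - implied), 5 * se)
  }
  # patient-level QoL prevalence at study scale stays in a plausible band
  # around the observed 6/31 rate
  prev_qol <- vapply(1:10, function(s) {
    co <- simulate_cohort(cohort_config(seed = s))
    mean(analysis_units(co, "qol")$event)
  }, numeric(1))
  expect_true(all(prev_qol >= 0.02 & prev_qol <= 0.40))
})

test_that("dose correlation is honoured through the copula", {
  co <- simulate_cohort(cohort_config(n_patients = 800, seed = 77,
                                      dose_correlation = 0.7))
  ipsi <- co$mean_dose_gy[co$laterality == "ipsilateral"]
  contra <- co$mean_dose_gy[co$laterality == "contralateral"]
  expect_gt(cor(ipsi, contra, method = "spearman"), 0.5)
})

test_that("simulate_dvh hits the target mean exactly and stays valid", {
  cv <- simulate_dvh(51.7, spread = 8, bins = 120, seed = 4)
  expect_s3_class(cv, "dvh_curve")
  expect_lt(abs(mean_dose(cv) - 51.7), 1e-6)
  expect_lt(abs(eud(cv, 1) - mean_dose(cv)), 1e-12)

  single <- simulate_dvh(30, spread = 0)
  expect_equal(single$dose, 30)
  expect_equal(single$volume, 1)
  expect_error(simulate_dvh(50, 5, bins = 0), ">= 1")
  expect_error(simulate_dvh(-1, 5), "> 0")
})

test_that("the caller's RNG stream is not disturbed", {
  set.seed(1); before <- runif(3)
  set.seed(1)
  invisible(simulate_cohort(cohort_config(seed = 99)))
  expect_identical(runif(3), before)
})
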