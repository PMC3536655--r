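test_that("meets_quantec implements the 20/25-Gy rule inclusively", {
  expect_true(meets_quantec(c(18, 60)))    # one gland spared below 20
  expect_true(meets_quantec(c(24, 25)))    # both at or below 25
  expect_false(meets_quantec(c(22, 30)))
  expect_true(meets_quantec(c(20, 70)))    # boundary counts as meeting
  expect_true(meets_quantec(15))           # single-gland patient
  expect_error(meets_quantec(numeric(0)), "1 or 2")
  expect_error(meets_quantec(c(1, 2, 3)), "1 or 2")
})

test_that("meets_quantec is monotone: lowering a dose never loses compliance", {
  set.seed(40)
  for (i in 1:200) {
    doses <- runif(2, 0, 80)
    if (meets_quantec(doses)) {
      expect_true(meets_quantec(doses * runif(1, 0.1, 1)))
      expect_true(meets_quantec(pmax(doses - runif(1, 0, 10), 0)))
    }
  }
})

test_that("cutoff classification predicts no event at or below the cutoff", {
  expect_false(classify_by_cutoff(20, 20))
  expect_true(classify_by_cutoff(20.01, 20))
  expect_false(classify_by_cutoff(43.6, 43.6))
  expect_error(classify_by_cutoff(-1, 20), ">= 0")
})

test_that("ppv and npv match hand arithmetic and their limits", {
  expect_equal(ppv(1, 1, 0.3), 1)
  expect_equal(ppv(0.8, 0.9, 0.2), 0.16 / 0.24)
  expect_equal(ppv(0.5, 0.5, 0), 0)
  expect_equal(npv(1, 0.9, 0.2), 1)
  expect_equal(npv(0.8, 0.9, 0.2), 0.72 / 0.76)
  expect_equal(npv(0.5, 0, 0.5), 0)
  expect_error(ppv(1.2, 0.5, 0.5), "\\[0, 1\\]")
  expect_warning(expect_true(is.na(ppv(0, 1, 0.5))), "undefined")
})

test_that("formula predictive values equal confusion-count ratios exactly", {
  set.seed(77)
  for (i in 1:50) {
    n <- sample(10:120, 1)
    dose <- runif(n, 5, 75)
    event <- runif(n) < ntcp(dose, lkb_params(td50 = 43.6, m = 0.25))
    if (all(event) || !any(event)) next
    tab <- predictive_values_at_cutoffs(data.frame(dose = dose, event = event),
                                        cutoffs = c(20, 25, 43.6, 44.1))
    for (j in seq_len(nrow(tab))) {
      with(tab[j, ], {
        if (tp + fp > 0) expect_equal(ppv, tp / (tp + fp))
        if (tn + fn > 0) expect_equal(npv, tn / (tn + fn))
        expect_equal(prevalence, (tp + fn) / (tp + fp + tn + fn))
      })
    }
  }
})

test_that("a hand-countable 10-unit set yields the expected table", {
  units <- data.frame(
    dose = c(10, 15, 22, 28, 35, 42, 48, 55, 62, 70),
    event = c(F, F, F, T, F, T, F, T, T, T)
  )
  tab <- predictive_values_at_cutoffs(units, cutoffs = 25)
  # above 25 Gy: 7 units, 5 events -> tp=5 fp=2; at/below: tn=3 fn=0
  expect_equal(tab$tp, 5)
  expect_equal(tab$fp, 2)
  expect_equal(tab$tn, 3)
  expect_equal(tab$fn, 0)
  expect_equal(tab$ppv, 5 / 7)
  expect_equal(tab$npv, 1)
})

test_that("NPV is 100% at 20 and 25 Gy when no events occur below 25 Gy", {
  # steep dose-response (m = 0.05) puts the event probability below 1e-17
  # at 25 Gy, so the premise 'no events below 25 Gy' holds by construction
  cfg <- cohort_config(n_patients = 200, seed = 314,
                       true_params_sef = lkb_params(td50 = 43.6, m = 0.05))
  co <- simulate_cohort(cfg)
  units <- analysis_units(co, "sef")
  stopifnot(!any(units$event[units$dose <= 25]))
  tab <- predictive_values_at_cutoffs(units, cutoffs = c(20, 25))
  expect_equal(tab$npv, c(1, 1))

  all_event <- data.frame(dose = c(10, 50), event = c(TRUE, TRUE))
  tab2 <- predictive_values_at_cutoffs(all_event, cutoffs = 25)
  expect_equal(tab2$npv, 0)   # the only predicted negative is an event
})

test_that("NPV never rises as the cutoff moves past event-carrying doses", {
  set.seed(88)
  for (i in 1:20) {
    n <- 150
    dose <- runif(n, 5, 75)
    event <- runif(n) < ntcp(dose, lkb_params(td50 = 40, m = 0.2))
    if (all(event) || !any(event)) next
    u <- data.frame(dose = dose, event = event)
    cuts <- seq(15, 65, by = 5)
    tab <- predictive_values_at_cutoffs(u, cutoffs = cuts)
    for (j in seq_len(length(cuts) - 1)) {
      passed <- u$event[u$dose > cuts[j] & u$dose <= cuts[j + 1]]
      # a step that only absorbs events into the negatives cannot raise NPV
      if (length(passed) > 0 && all(passed) &&
          !is.na(tab$npv[j]) && !is.na(tab$npv[j + 1])) {
        expect_lte(tab$npv[j + 1], tab$npv[j] + 1e-12)
      }
    }
  }
})
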