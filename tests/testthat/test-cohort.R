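test_that("an inert cohort accrues the discounted geometric QALY series", {
  p <- toy_inert_params()
  tr <- run_cohort(p, no_screening())
  expect_equal(tr$discounted_qaly, sum(1.03^-(0:49)), tolerance = 1e-12)
  expect_equal(tr$discounted_cost, 0)
  expect_true(all(tr$cycles$Healthy == 1))
  cep <- ce_point(tr)
  expect_equal(cep$effect, sum(1.03^-(0:49)), tolerance = 1e-12)

  # discount rate 0: exactly one QALY per cycle
  p0 <- toy_inert_params(discount_rate = 0)
  expect_equal(run_cohort(p0, no_screening())$discounted_qaly, 50)
})

test_that("two-cycle single-stage toy matches the hand-computed tree", {
  p <- zero_costs(toy_single_stage_params(lambda = 0.1, n_cycles = 2))
  tr <- run_cohort(p, no_screening())
  # cycle 0: everyone healthy (QALY 1); 10% diagnosed into utility 0.8
  expect_equal(tr$cycles$Healthy, c(1, 0.9))
  expect_equal(tr$cycles$II, c(0, 0.1))
  expect_equal(tr$discounted_qaly, 1 + (0.9 * 1 + 0.1 * 0.8),
               tolerance = 1e-12)
})

test_that("engine agrees with the hand-enumerated oracle on small models", {
  cases <- list(
    list(lambda = 0.1, mu = 0, mort = 0, n = 4, r = 0, screens = integer()),
    list(lambda = 0.05, mu = 0.02, mort = 0.1, n = 10, r = 0.03,
         screens = integer()),
    list(lambda = 0.08, mu = 0.01, mort = 0.05, n = 8, r = 0.05,
         screens = c(35, 37, 39)),
    list(lambda = 0.2, mu = 0.005, mort = 0.3, n = 12, r = 0,
         screens = c(36, 40, 44))
  )
  for (cs in cases) {
    p <- toy_single_stage_params(lambda = cs$lambda, n_cycles = cs$n,
                                 discount_rate = cs$r,
                                 mu_other = cs$mu, mort_II = cs$mort)
    strat <- if (length(cs$screens))
      screening_strategy(min(cs$screens), max(cs$screens),
                         if (length(cs$screens) > 1)
                           diff(cs$screens)[1] else 1)
    else no_screening()
    tr <- run_cohort(p, strat)
    orc <- oracle_single_stage(p, screen_ages = cs$screens)
    expect_equal(tr$discounted_cost, orc$cost, tolerance = 1e-12)
    expect_equal(tr$discounted_qaly, orc$qaly, tolerance = 1e-12)
  }
})

test_that("screening-round costing follows the triage pathway formula", {
  p <- default_parameters()
  expect_equal(screening_cycle_cost(p, 0, 0),
               list(cost = 0, detected = 0))
  full <- screening_cycle_cost(p, 1, 0)
  expect_equal(full$cost, 33 + 120 + 0.229 * 249.33 + 0.033 * 184,
               tolerance = 1e-9)
  expect_equal(full$detected, 0)
  d <- screening_cycle_cost(p, 1, 0.001)
  expect_equal(d$detected, 0.000851, tolerance = 1e-12)
})

test_that("every base-case trace conserves mass, with monotone deaths", {
  p <- default_parameters()
  for (strat in list(no_screening(), screening_strategy(35, 65, 2),
                     screening_strategy(45, 74, 1),
                     screening_strategy(40, 69, 3))) {
    tr <- run_cohort(p, strat)
    occ <- tr$cycles[, c("Healthy", "DCIS", "I", "II", "III", "IV",
                         "Death_BC", "Death_Other")]
    expect_true(all(abs(rowSums(occ) - 1) < 1e-9))
    expect_true(all(diff(tr$cycles$Death_BC) >= 0))
    expect_true(all(diff(tr$cycles$Death_Other) >= 0))
    expect_true(all(tr$cycles$cost_total >= 0))
    expect_lte(tr$discounted_cost, tr$undiscounted_cost)
    expect_lte(tr$discounted_qaly, tr$undiscounted_qaly)
  }
})

test_that("structural sanity: label independence, frequency monotonicity, zero-sensitivity equivalence", {
  p <- default_parameters()

  # with screening disabled the CE point ignores the schedule entirely
  t_none <- run_cohort(p, no_screening())
  expect_equal(t_none$discounted_cost,
               run_cohort(p, no_screening())$discounted_cost)

  # screening cost component non-decreasing in screening frequency
  costs <- vapply(c(3, 2, 1), function(iv)
    sum(run_cohort(p, screening_strategy(40, 65, iv))$cycles$cost_screening),
    numeric(1))
  expect_true(all(diff(costs) > 0))

  # zero sensitivity: stage mix at diagnosis equals the no-screening arm
  p0 <- p
  p0$test$sensitivity[c("base", "low", "high")] <- 0
  t_scr <- run_cohort(p0, screening_strategy(35, 65, 2))
  stage_cols <- c("DCIS", "I", "II", "III", "IV", "Death_BC")
  expect_equal(t_scr$cycles[, stage_cols], t_none$cycles[, stage_cols],
               tolerance = 1e-12)
  expect_equal(t_scr$discounted_qaly, t_none$discounted_qaly,
               tolerance = 1e-12)
  expect_gt(t_scr$discounted_cost, t_none$discounted_cost)

  # discounting at rate zero leaves totals undiscounted
  pz <- p
  pz$econ$discount_rate <- 0
  tz <- run_cohort(pz, screening_strategy(35, 65, 2))
  expect_equal(tz$discounted_cost, tz$undiscounted_cost)
})

test_that("engine options change the structure in the documented direction", {
  p <- default_parameters()
  s <- screening_strategy(35, 65, 2)
  base <- run_cohort(p, s)

  hc <- run_cohort(p, s, cohort_options(half_cycle = TRUE))
  expect_false(isTRUE(all.equal(hc$discounted_qaly, base$discounted_qaly)))
  occ <- hc$cycles[, c("Healthy", "DCIS", "I", "II", "III", "IV",
                       "Death_BC", "Death_Other")]
  expect_true(all(abs(rowSums(occ) - 1) < 1e-9))

  # one-cycle diagnostic delay for missed cases defers, never creates, mass
  carry <- run_cohort(p, s, cohort_options(missed_carryover = TRUE))
  occ2 <- carry$cycles[, c("Healthy", "DCIS", "I", "II", "III", "IV",
                           "Death_BC", "Death_Other")]
  expect_true(all(abs(rowSums(occ2) - 1) < 1e-9))
  expect_lt(abs(carry$discounted_qaly - base$discounted_qaly), 0.01)
})
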