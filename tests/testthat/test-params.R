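test_that("packaged base case carries the printed model inputs and is valid", {
  p <- default_parameters()
  expect_length(validate_parameters(p), 0)

  expect_equal(p$progression$p_III_IV, 0.21)
  expect_equal(p$progression$mort[["IV"]], 0.2331)
  expect_equal(p$progression$rr_dcis, 2.02)
  expect_equal(p$utilities[["IV"]], 0.3)
  expect_equal(p$utilities[["Healthy"]], 1)
  expect_equal(p$test$sensitivity[["base"]], 0.851)
  expect_equal(p$test$specificity[["base"]], 0.967)
  expect_equal(p$screening_costs$c_mam, 249.33)
  expect_equal(p$screening_costs$f_mam, 0.229)
  expect_equal(p$screening_costs$f_referral_pos, 0.023)
  expect_equal(p$econ$wtp_3x, 3 * p$econ$gdp_per_capita)

  # stage shares sum to one in both detection modes
  expect_equal(sum(p$stage_screen), 1, tolerance = 1e-6)
  expect_equal(sum(p$stage_clinical), 1, tolerance = 1e-6)
  expect_equal(unname(p$stage_clinical),
               c(0.0588, 0.2652, 0.457, 0.1529, 0.0661))

  # mortality decomposition holds on every band
  m <- p$mortality
  expect_true(all(abs(m$mu_other - (m$mu_all - m$mu_bc)) <= 1e-6))
  expect_equal(age_lookup(m, 37, "mu_other"), 0.000482)

  # age lookup covers 35-85 with unique bands
  for (a in c(35, 39, 40, 64, 65, 84, 85)) {
    expect_silent(age_lookup(p$incidence, min(a, 80), "lambda"))
    expect_silent(age_lookup(m, a, "mu_other"))
  }
})

test_that("validation reports each broken invariant without raising", {
  p <- default_parameters()
  p$utilities[["DCIS"]] <- 1.2
  v <- validate_parameters(p)
  expect_true(any(grepl("utility out of \\[0,1\\]", v)))

  p2 <- default_parameters()
  p2$mortality$mu_other[3] <- p2$mortality$mu_other[3] + 0.01
  v2 <- validate_parameters(p2)
  expect_length(grep("mu_other", v2), 1)
  expect_match(v2, "45-49", all = FALSE)

  p3 <- default_parameters()
  p3$stage_clinical[["IV"]] <- 0.2
  expect_true(any(grepl("stage_clinical shares sum", validate_parameters(p3))))

  p4 <- default_parameters()
  p4$progression$mort[["IV"]] <- 0.95  # + worst-case mu_other > 1
  expect_true(any(grepl("stage IV", validate_parameters(p4))))
  expect_error(run_cohort(p4, no_screening()), "stage IV")
})

test_that("config loading overrides, validates and round-trips", {
  p <- default_parameters()

  p5 <- load_parameters(list(econ = list(discount_rate = 0.05)))
  expect_equal(p5$econ$discount_rate, 0.05)
  p5$econ$discount_rate <- p$econ$discount_rate
  expect_equal(p5, p, tolerance = 1e-12)

  expect_error(load_parameters(list(utilities = list(Healthy = 1.2))),
               "utility out of \\[0,1\\]")
  expect_error(load_parameters(list(nonsense = 1)), "unknown section")
  expect_error(load_parameters(file.path(tempdir(), "absent.yaml")),
               "not found")

  f <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(p, f)
  expect_equal(load_parameters(f), p, tolerance = 1e-9)

  # age-banded table referenced as CSV
  csv <- withr::local_tempfile(fileext = ".csv")
  inc <- p$incidence
  inc$lambda <- inc$lambda * 2
  write.csv(inc, csv, row.names = FALSE)
  p6 <- load_parameters(list(incidence = csv))
  expect_equal(p6$incidence$lambda, p$incidence$lambda * 2)
})

test_that("parameter paths read and write scalars and ranged values", {
  p <- default_parameters()
  expect_equal(param_get(p, "econ.discount_rate"), 0.03)
  expect_equal(param_get(p, "utilities.IV"), 0.3)
  expect_equal(param_get(p, "stage_costs.IV.c_outpatient"), 4928)
  expect_equal(param_get(p, "test.sensitivity"), 0.851)
  expect_error(param_get(p, "no.such.param"), "unknown parameter")

  p2 <- param_set(p, "utilities.IV", 0.35)
  expect_equal(param_get(p2, "utilities.IV"), 0.35)
  p3 <- param_set(p, "stage_costs.IV.c_outpatient", 60000)
  expect_equal(param_get(p3, "stage_costs.IV.c_outpatient"), 60000)
  # range widens to keep the set valid when a draw exceeds the range
  expect_equal(p3$stage_costs$IV$c_outpatient[["high"]], 60000)
  expect_length(validate_parameters(p3), 0)
  expect_error(param_set(p, "stage_costs.IV.bogus", 1), "unknown parameter")
})
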