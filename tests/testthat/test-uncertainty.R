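test_that("one-way sensitivity re-runs the model at the range ends", {
  p <- default_parameters()
  pair <- default_pair()

  # degenerate range: no swing
  deg <- data.frame(param = "screening_costs.c_us", base = 120,
                    low = 120, high = 120)
  expect_equal(one_way(p, deg, pair)$swing, 0)

  # toy where the incremental cost is proportional to one unit cost:
  # doubling it doubles the ICUR
  toy <- zero_costs(toy_single_stage_params(lambda = 0.05, n_cycles = 10,
                                            discount_rate = 0))
  # screen-detected cases land in stage I (utility 0.9) instead of II
  # (0.8), so screening buys QALYs while its only cost is the CBE fee
  toy$stage_screen[] <- c(0, 1, 0, 0, 0)
  toy$screening_costs$c_cbe <- 50
  toy$screening_costs$f_mam <- 0
  rng <- data.frame(param = "screening_costs.c_cbe", base = 50,
                    low = 50, high = 100)
  tp <- list(no_screening(), screening_strategy(35, 44, 1))
  ow <- one_way(toy, rng, tp)
  expect_equal(ow$icur_at_high, 2 * ow$icur_at_low, tolerance = 1e-9)

  expect_error(
    one_way(p, data.frame(param = "bogus.path", base = 1, low = 0,
                          high = 2), pair),
    "unknown parameter")
})

test_that("tornado sorts by swing and ignores input order", {
  p <- default_parameters()
  pair <- default_pair()
  ranges <- default_dsa_ranges(p)
  expect_gt(nrow(ranges), 30)
  expect_true(all(ranges$low <= ranges$base & ranges$base <= ranges$high))

  sub <- ranges[ranges$param %in%
                  c("econ.discount_rate", "screening_costs.c_us",
                    "test.sensitivity", "utilities.IV"), ]
  tor <- tornado(p, sub, pair)
  expect_equal(nrow(tor), 4)
  expect_true(all(diff(tor$swing) <= 0))

  shuffled <- tornado(p, sub[c(3, 1, 4, 2), ], pair)
  expect_equal(shuffled, tor, ignore_attr = TRUE)

  single <- tornado(p, sub[1, ], pair)
  expect_equal(nrow(single), 1)
})

test_that("distribution assignment matches the method-of-moments oracle", {
  p <- default_parameters()
  ranges <- default_dsa_ranges(p)
  specs <- assign_distributions(p, ranges)

  # independent oracle for the sensitivity beta shapes
  m <- 0.851
  s <- (0.944 - 0.758) / 3.92
  nu <- m * (1 - m) / s^2 - 1
  sens <- specs[specs$param == "test.sensitivity", ]
  expect_equal(sens$family, "beta")
  expect_equal(sens$shape1, m * nu, tolerance = 1e-9)
  expect_equal(sens$shape2, (1 - m) * nu, tolerance = 1e-9)
  expect_equal(sens$shape1, 47.08, tolerance = 1e-3)
  expect_equal(sens$shape2, 8.24, tolerance = 1e-3)

  # gamma means equal the base value by construction
  gam <- specs[specs$family == "gamma", ]
  expect_gt(nrow(gam), 0)
  expect_equal(gam$shape * gam$scale, gam$base, tolerance = 1e-9)

  # zero-width range: flagged point mass
  pm <- assign_distributions(p, data.frame(
    param = "screening_costs.c_biopsy", base = 184, low = 184, high = 184))
  expect_equal(pm$family, "point")
})

test_that("PSA is seed-deterministic with stable per-parameter substreams", {
  p <- default_parameters()
  pair <- list(screening_strategy(45, 65, 3), screening_strategy(35, 65, 2))
  specs <- default_psa_distributions(p)

  a <- run_psa(p, specs, pair, n_iterations = 25, seed = 7)
  b <- run_psa(p, specs, pair, n_iterations = 25, seed = 7)
  expect_identical(a$draws, b$draws)
  expect_equal(a$acceptability, b$acceptability)

  c <- run_psa(p, specs, pair, n_iterations = 25, seed = 8)
  expect_false(identical(a$draws, c$draws))

  # dropping a parameter leaves every other parameter's draws unchanged
  s1 <- sample_distributions(specs, seed = 7, iteration = 3)
  s2 <- sample_distributions(specs[-1, ], seed = 7, iteration = 3)
  common <- intersect(names(s1$values), names(s2$values))
  expect_equal(s1$values[common], s2$values[common])
})

test_that("sampled parameters recover their base values in the mean", {
  p <- default_parameters()
  specs <- default_psa_distributions(p)
  picks <- specs[specs$param %in%
                   c("test.sensitivity", "utilities.IV",
                     "stage_costs.IV.c_outpatient",
                     "screening_costs.c_us"), ]
  n <- 10000
  draws <- vapply(seq_len(n), function(it)
    sample_distributions(picks, seed = 99, iteration = it)$values,
    numeric(nrow(picks)))
  for (i in seq_len(nrow(picks))) {
    sdev <- if (picks$family[i] == "beta") {
      a <- picks$shape1[i]; b <- picks$shape2[i]
      sqrt(a * b / ((a + b)^2 * (a + b + 1)))
    } else sqrt(picks$shape[i]) * picks$scale[i]
    expect_lt(abs(mean(draws[i, ]) - picks$base[i]), 3 * sdev / sqrt(n))
  }
})

test_that("acceptability applies the net-benefit rule", {
  mk <- function(dc, de) {
    r <- structure(list(
      draws = data.frame(iteration = seq_along(dc), delta_cost = dc,
                         delta_effect = de),
      n_iterations = length(dc), seed = 1, wtp = 537000,
      acceptability = NA, ellipse = NULL, redraws = 0L),
      class = "bc_psa")
    r
  }
  # cost-saving and effective draws are always acceptable
  expect_equal(acceptability(mk(c(-10, -5), c(0.1, 0.2)), 0), 1)
  # at WTP 0 only cost-saving draws count
  expect_equal(acceptability(mk(c(-10, 5, 0), c(1, 1, 1)), 0), 2 / 3)
  # negative effect with positive cost is never acceptable
  expect_equal(acceptability(mk(10, -0.1), 537000), 0)
  # monotone in WTP when all effects are positive
  r <- mk(c(100, 5000, 20000), c(0.01, 0.01, 0.01))
  accs <- vapply(c(0, 1e4, 1e6, 1e8), function(w) acceptability(r, w),
                 numeric(1))
  expect_true(all(diff(accs) >= 0))
})

test_that("confidence ellipse matches the closed-form scaling", {
  set.seed(11)
  sigma <- matrix(c(4, 1.2, 1.2, 1), 2)
  ch <- chol(sigma)
  xy <- matrix(rnorm(4000), ncol = 2) %*% ch
  e <- confidence_ellipse(xy)
  expect_equal(e$scale, qchisq(0.95, 2))
  expect_equal(e$center, colMeans(xy))
  ev <- eigen(cov(xy), symmetric = TRUE)$values
  expect_equal(e$semi_axes, sqrt(qchisq(0.95, 2) * ev), tolerance = 1e-12)
  expect_true(isSymmetric(e$cov))
  expect_true(all(eigen(e$cov)$values >= 0))

  # degenerate: all specs point masses give identical iterations
  p <- default_parameters()
  pm <- data.frame(param = "screening_costs.c_us", family = "point",
                   shape1 = NA, shape2 = NA, shape = NA, scale = NA,
                   base = 120)
  r <- run_psa(p, pm, default_pair(), n_iterations = 3, seed = 5)
  expect_equal(var(r$draws$delta_cost), 0)
  expect_true(r$acceptability %in% c(0, 1))
})
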