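test_that("fraction vaccinated among positives follows the odds-ratio identity", {
  expect_equal(vacc_frac_positives(0.3, 0), 0.3)
  expect_equal(vacc_frac_positives(0.3, 1), 0)
  expect_equal(vacc_frac_positives(0.3, 0.95), 0.015 / 0.715)

  # monotone decreasing in VE, and the implied OR equals 1 - VE
  for (p_n in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    ve_grid <- seq(0, 0.99, by = 0.01)
    p_i <- vacc_frac_positives(p_n, ve_grid)
    expect_true(all(diff(p_i) < 0))
    or <- (p_i / (1 - p_i)) / (p_n / (1 - p_n))
    expect_equal(or, 1 - ve_grid, tolerance = 1e-12)
  }
  expect_error(vacc_frac_positives(0, 0.5), class = "tnd_invalid_parameter")
  expect_error(vacc_frac_positives(0.3, 1.1), class = "tnd_invalid_parameter")
})

test_that("percent positivity matches the closed form and its limits", {
  expect_equal(percent_positivity(0.3, 0.5, Lambda_I = 0.4, Lambda_N = 0), 1)
  expect_equal(percent_positivity(0.3, 0.95, 0.1, 0.2), 0.253846178874,
               tolerance = 1e-10)
  # with no vaccine effect the coverage drops out
  expect_equal(percent_positivity(0.2, 0, 0.1, 0.2), 0.322407336766,
               tolerance = 1e-10)
  expect_equal(percent_positivity(0.8, 0, 0.1, 0.2),
               percent_positivity(0.2, 0, 0.1, 0.2))
  expect_error(percent_positivity(0.3, 0.5, 0, 0),
               class = "tnd_invalid_parameter")

  # decreasing in coverage*VE and in Lambda_N; interior when both active
  pis <- percent_positivity(0.5, seq(0, 0.9, 0.1), 0.1, 0.2)
  expect_true(all(diff(pis) < 0))
  pis_n <- sapply(c(0.1, 0.2, 0.4), function(l)
    percent_positivity(0.5, 0.9, 0.1, l))
  expect_true(all(diff(pis_n) < 0))
  expect_true(all(pis > 0 & pis < 1))
})

test_that("unit cell counts and the implied source population size", {
  d <- ref_design(ve = 0.95, coverage = 0.3)
  u <- unit_cell_counts(d)
  expect_equal(unname(u), c(0.00142743872946, 0.06, 0.0666138073748, 0.14),
               tolerance = 1e-10)
  # algebraic identities of the construction
  expect_equal(unname(u["a"] + u["c"]),
               (1 - 0.3 * 0.95) * (1 - exp(-0.1)), tolerance = 1e-12)
  expect_equal(unname(u["b"] / u["d"]), 0.3 / 0.7, tolerance = 1e-15)

  expect_equal(source_population_size(74, u), 277L)
  u1 <- unit_cell_counts(ref_design(ve = 0.95, coverage = 0.1))
  expect_equal(source_population_size(228, u1), 797L)
  expect_equal(source_population_size(1000, c(0.25, 0.25, 0.25, 0.25)), 1000L)
  expect_error(source_population_size(10, c(0, 0, 0, 0)),
               class = "tnd_invalid_parameter")
})

test_that("score variance components reproduce hand-computed values", {
  v <- score_variances(0.0209790, 0.3, 0.253846)
  expect_equal(unname(v["sigma0_sq"]), 0.9326523, tolerance = 1e-6)
  expect_equal(unname(v["sigma1_sq"]), 0.1406482, tolerance = 1e-6)
  v2 <- score_variances(0.0476190, 0.5, 0.199873)
  expect_equal(unname(v2["sigma0_sq"]), 1.512123, tolerance = 1e-6)
  expect_equal(unname(v2["sigma1_sq"]), 0.3390562, tolerance = 1e-6)

  # under no effect (p_I = p_N = p) the null variance reduces to
  # p(1-p)/(pi(1-pi))
  for (p in c(0.2, 0.5, 0.8)) {
    for (pi in c(0.1, 0.3, 0.6)) {
      expect_equal(unname(score_variances(p, p, pi)["sigma0_sq"]),
                   p * (1 - p) / (pi * (1 - pi)), tolerance = 1e-12)
    }
  }
  expect_error(score_variances(0.1, 0.3, 1), class = "tnd_invalid_parameter")
})

test_that("multinomial alternative variance matches the closed form", {
  expect_equal(multinomial_variance(0, 0, 0.5), 0)
  expect_equal(multinomial_variance(0.0209790, 0.3, 0.253846), 0.3749414,
               tolerance = 1e-6)
  # diverges toward the boundary
  expect_gt(multinomial_variance(0.02, 0.3, 1e-9), 1e7)
  expect_error(multinomial_variance(0.02, 0.3, 0),
               class = "tnd_undefined_variance")
  expect_error(multinomial_variance(0.02, 0.3, 1),
               class = "tnd_undefined_variance")
})

test_that("design constructor validates parameters and paths", {
  d <- tnd_design(0.95, 0.3, Lambda_I = 0.1, Lambda_N = 0.2)
  expect_s3_class(d, "tnd_design")
  expect_equal(d$p_i, 0.015 / 0.715)
  expect_equal(d$pi, 0.253846178874, tolerance = 1e-10)

  # rate and cumulative parameterisations agree
  d2 <- ref_design(0.95, 0.3)
  expect_equal(d2$pi, d$pi)
  expect_equal(d2$Lambda_I, 0.1)

  expect_error(tnd_design(1, 0.3, Lambda_I = 0.1, Lambda_N = 0.2),
               class = "tnd_invalid_parameter")
  expect_error(tnd_design(0.9, 1.2, Lambda_I = 0.1, Lambda_N = 0.2),
               class = "tnd_invalid_parameter")
  expect_error(tnd_design(0.9, 0.3, lambda_i = 0.001, lambda_n = 0.002,
                          tau = 100, Lambda_I = 0.1, Lambda_N = 0.2),
               class = "tnd_invalid_parameter")
  expect_error(tnd_design(0.9, 0.3, lambda_i = 0.001, lambda_n = 0.002,
                          tau = 100, pi = 0.3),
               class = "tnd_invalid_parameter")
  expect_error(tnd_design(0.9, 0.3), class = "tnd_invalid_parameter")

  # surveillance-pi design supports sizing but not event simulation
  d3 <- tnd_design(0.95, 0.3, pi = 0.25)
  expect_equal(d3$pi, 0.25)
  expect_error(unit_cell_counts(d3), class = "tnd_invalid_parameter")
})
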