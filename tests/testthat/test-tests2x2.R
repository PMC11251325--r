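# independent oracle for the general-null score test: numerical score and
# observed information of the binomial logistic log-likelihood, with the
# intercept profiled out by the efficient information
numeric_score_stat <- function(a, b, c, d, theta0) {
  loglik <- function(b0, b1) {
    p1 <- plogis(b0 + b1)
    p0 <- plogis(b0)
    a * log(p1) + b * log(1 - p1) + c * log(p0) + d * log(1 - p0)
  }
  # constrained intercept by direct 1-d optimisation
  b0 <- optimize(function(b0) loglik(b0, log(theta0)),
                 interval = c(-30, 30), maximum = TRUE, tol = 1e-12)$maximum
  h <- 1e-5
  U <- (loglik(b0, log(theta0) + h) - loglik(b0, log(theta0) - h)) / (2 * h)
  d2 <- function(f) (f(h) - 2 * f(0) + f(-h)) / h^2
  I11 <- -d2(function(e) loglik(b0, log(theta0) + e))
  I00 <- -d2(function(e) loglik(b0 + e, log(theta0)))
  I01 <- -(loglik(b0 + h, log(theta0) + h) - loglik(b0 + h, log(theta0) - h) -
             loglik(b0 - h, log(theta0) + h) + loglik(b0 - h, log(theta0) - h)) /
    (4 * h^2)
  U / sqrt(I11 - I01^2 / I00)
}

random_tables <- function(n_tables, seed, lambda = 15) {
  set.seed(seed)
  out <- vector("list", n_tables)
  i <- 1
  while (i <= n_tables) {
    cells <- rpois(4, lambda)
    tb <- matrix(cells, 2)
    if (all(rowSums(tb) > 0) && all(colSums(tb) > 0)) {
      out[[i]] <- cells
      i <- i + 1
    }
  }
  out
}

test_that("log odds ratio handles continuity correction and zero cells", {
  expect_equal(log_odds_ratio(tnd_table(5, 20, 15, 60)), 0)
  expect_equal(log_odds_ratio(tnd_table(0, 30, 20, 50), delta = 0.5),
               -3.20932541404, tolerance = 1e-9)
  expect_error(log_odds_ratio(tnd_table(0, 30, 20, 50)),
               class = "tnd_intractable")
  expect_error(log_odds_ratio(tnd_table(1, 2, 3, 4), delta = -1),
               class = "tnd_invalid_parameter")
})

test_that("Wald test: statistic, rejection rule and intractability", {
  r <- wald_test(tnd_table(5, 20, 15, 60))
  expect_equal(r$statistic, 0)
  expect_false(r$reject)

  r0 <- wald_test(tnd_table(0, 30, 20, 50))
  expect_false(r0$tractable)
  expect_false(r0$reject)
  expect_true(is.na(r0$statistic))

  r2 <- wald_test(tnd_table(2, 28, 25, 45))
  expect_equal(r2$statistic, -2.652745, tolerance = 1e-6)
  expect_true(r2$reject)  # below qnorm(0.025) = -1.96
  expect_equal(r2$p_value, pnorm(r2$statistic))
})

test_that("continuity-corrected Wald test and its delta -> 0 limit", {
  r <- wald_cc_test(tnd_table(0, 30, 20, 50))
  expect_true(r$tractable)
  expect_equal(r$statistic, -2.21392323482, tolerance = 1e-9)
  expect_true(r$reject)

  # symmetric tables have corrected OR 1, so the statistic is
  # -ln(theta0)/sqrt(4/(k+delta))
  for (k in c(1, 7)) {
    r <- wald_cc_test(tnd_table(k, k, k, k), theta0 = 2, delta = 0.5)
    expect_equal(r$statistic, -log(2) / sqrt(4 / (k + 0.5)), tolerance = 1e-12)
  }

  # continuity with the uncorrected test on all-positive tables
  for (cells in random_tables(20, seed = 7)) {
    cells <- cells + 1  # ensure strictly positive
    tb <- tnd_table(cells[1], cells[2], cells[3], cells[4])
    expect_equal(wald_cc_test(tb, delta = 1e-8)$statistic,
                 wald_test(tb)$statistic, tolerance = 1e-6)
  }
})

test_that("score test closed form, zero-cell tractability and antisymmetry", {
  expect_equal(score_test(tnd_table(5, 20, 15, 60))$statistic, 0)
  r <- score_test(tnd_table(0, 30, 20, 50))
  expect_true(r$tractable)
  expect_equal(r$statistic, -3.27326835354, tolerance = 1e-9)
  expect_true(r$reject)

  # zero margin is intractable even for the score test
  r2 <- score_test(tnd_table(0, 0, 20, 50))
  expect_false(r2$tractable)
  expect_false(r2$reject)

  # swapping vaccinated/unvaccinated rows negates the statistic
  for (cells in random_tables(25, seed = 11)) {
    s1 <- score_test(tnd_table(cells[1], cells[2], cells[3], cells[4]))$statistic
    s2 <- score_test(tnd_table(cells[3], cells[4], cells[1], cells[2]))$statistic
    expect_equal(s1, -s2, tolerance = 1e-12)
  }
})

test_that("constrained-likelihood score path agrees with the closed form at OR = 1", {
  for (cells in random_tables(200, seed = 42)) {
    closed <- score_test(tnd_table(cells[1], cells[2], cells[3], cells[4]))$statistic
    general <- tnddesign:::score_stat_general(cells[1], cells[2], cells[3],
                                              cells[4], theta0 = 1)
    expect_equal(general, closed, tolerance = 1e-8)
  }
})

test_that("general-null score test matches a numerical likelihood oracle", {
  for (cells in random_tables(25, seed = 99)) {
    for (theta0 in c(0.5, 1.7)) {
      got <- score_test(tnd_table(cells[1], cells[2], cells[3], cells[4]),
                        theta0 = theta0)$statistic
      want <- numeric_score_stat(cells[1], cells[2], cells[3], cells[4], theta0)
      expect_equal(got, want, tolerance = 1e-4)
    }
  }
})
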