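test_that("the Q function matches quadrature of the Gaussian tail", {
  expect_equal(q_function(0), 0.5)
  expect_equal(q_function(Inf), 0)
  expect_equal(q_function(-Inf), 1)
  expect_equal(q_function(1), quad_tail(1), tolerance = 1e-9)
  expect_lt(abs(q_function(1) - 0.158655), 1e-6)
  expect_equal(q_function(-2.3), quad_tail(-2.3), tolerance = 1e-9)
})

test_that("overall error is the prior-weighted sum of the component errors", {
  # the worked identity: P_FA = 0.18 and P_M = 0.31 under equal priors
  expect_equal(overall_error(0.18, 0.31, 0.5, 0.5), 0.245)
  expect_equal(overall_error(0, 0), 0)
  expect_equal(overall_error(1, 0, prior0 = 0.3), 0.3)
  expect_error(overall_error(0.5, 0.5, 0.6, 0.6), "sum to 1")
  expect_error(overall_error(1.2, 0), "\\[0, 1\\]")
})

test_that("closed-form errors match the symmetric and two-root oracles", {
  pr <- decision_problem(gaussian_model(0, 1), gaussian_model(2, 1))
  rep1 <- closed_form_errors(pr)
  expect_equal(rep1$p_fa, quad_tail(1), tolerance = 1e-9)
  expect_equal(rep1$p_m, quad_tail(1), tolerance = 1e-9)
  expect_equal(rep1$p_e, quad_tail(1), tolerance = 1e-9)

  # two-root case: P_FA = mass of both tails beyond +/- x_th under H0
  pr2 <- decision_problem(gaussian_model(0, 1), gaussian_model(0, 4))
  rep2 <- closed_form_errors(pr2)
  xth <- sqrt((8 / 3) * log(2))
  expect_equal(rep2$p_fa, 2 * quad_tail(xth), tolerance = 1e-9)
  pm_oracle <- stats::integrate(function(x) exp(-x^2 / 8) / sqrt(8 * pi),
                                -xth, xth, rel.tol = 1e-12)$value
  expect_equal(rep2$p_m, pm_oracle, tolerance = 1e-9)

  # identical models: no separability, P_FA + P_M = 1
  same <- decision_problem(gaussian_model(0, 1), gaussian_model(0, 1))
  suppressWarnings(rep3 <- closed_form_errors(same))
  expect_equal(rep3$p_fa + rep3$p_m, 1)
  expect_equal(rep3$p_e, 0.5)
})

test_that("every report satisfies the weighted-sum identity", {
  set.seed(55)
  for (rep in 1:10) {
    pr <- random_problem_1d()
    r <- closed_form_errors(pr)
    expect_equal(r$p_e, pr$prior0 * r$p_fa + pr$prior1 * r$p_m, tolerance = 1e-12)
    expect_true(all(c(r$p_fa, r$p_m, r$p_e) >= 0 & c(r$p_fa, r$p_m, r$p_e) <= 1))
  }
})

test_that("Monte Carlo errors agree with the closed form in 1-D and 2-D", {
  pr <- decision_problem(gaussian_model(0, 1), gaussian_model(2, 1))
  mc <- monte_carlo_errors(pr, n = 1e5, seed = 21)
  cf <- closed_form_errors(pr)
  expect_lt(abs(mc$p_fa - cf$p_fa), 3 * mc$mc_stderr["p_fa"] + 1e-12)
  expect_lt(abs(mc$p_m - cf$p_m), 3 * mc$mc_stderr["p_m"] + 1e-12)

  # separable 2-D problem: the 1-D closed form is the oracle
  pr2 <- decision_problem(gaussian_model(c(0, 0), diag(2)),
                          gaussian_model(c(2, 0), diag(2)))
  mc2 <- monte_carlo_errors(pr2, n = 1e5, seed = 22)
  expect_lt(abs(mc2$p_fa - cf$p_fa), 3 * mc2$mc_stderr["p_fa"] + 1e-12)

  expect_error(monte_carlo_errors(pr, n = 10, seed = 1), "at least 1000")
  expect_error(monte_carlo_errors(pr, n = 1e4), "seed")
})

test_that("identical models give complementary Monte Carlo regions", {
  same <- decision_problem(gaussian_model(c(1, 1), diag(2)),
                           gaussian_model(c(1, 1), diag(2)))
  mc <- monte_carlo_errors(same, n = 1000, seed = 3)
  expect_identical(mc$p_fa + mc$p_m, 1)
})

test_that("discriminant counting equals Monte Carlo on shared draws", {
  set.seed(66)
  for (rep in 1:5) {
    pr <- random_problem_2d(equal_priors = FALSE)
    n <- 5000L
    seed <- 1000L + rep
    mc <- monte_carlo_errors(pr, n = n, seed = seed)
    set.seed(seed)
    d0 <- sample_gaussian(pr$h0, n)
    d1 <- sample_gaussian(pr$h1, n)
    emp <- empirical_count_errors(pr, d0, d1)
    expect_identical(emp$p_fa, mc$p_fa)
    expect_identical(emp$p_m, mc$p_m)
  }
})

test_that("discriminant counting handles clear-cut and boundary points", {
  pr <- decision_problem(gaussian_model(0, 1), gaussian_model(10, 1))
  far0 <- matrix(rep(0, 5), ncol = 1)
  far1 <- matrix(rep(10, 5), ncol = 1)
  r <- empirical_count_errors(pr, far0, far1)
  expect_equal(r$p_fa, 0)
  expect_equal(r$p_m, 0)
  # a point exactly on the boundary (ln L = ln gamma) decides H0: no false alarm
  prs <- decision_problem(gaussian_model(0, 1), gaussian_model(2, 1))
  rb <- empirical_count_errors(prs, matrix(1), matrix(1))
  expect_equal(rb$p_fa, 0)
  expect_equal(rb$p_m, 1)
  expect_error(empirical_count_errors(pr, matrix(numeric(0), ncol = 1), far1),
               "nonempty")
})

test_that("the optimal threshold minimizes the overall error", {
  set.seed(44)
  for (rep in 1:10) {
    # alternate equal-variance (single-root) and generic (two-root) problems
    pr <- if (rep %% 2 == 0) {
      s <- runif(1, 0.2, 2)^2
      decision_problem(gaussian_model(runif(1, -2, 0), s),
                       gaussian_model(runif(1, 0.5, 2), s),
                       prior0 = runif(1, 0.2, 0.8))
    } else random_problem_1d()
    b <- solve_univariate_threshold(pr)
    if (length(b$roots) == 0L) next
    p_opt <- closed_form_errors(pr, b)$p_e
    for (delta in seq(0.05, 0.5, length.out = 20) * sample(c(-1, 1), 1)) {
      expect_gte(closed_form_errors(pr, shift_boundary(b, delta))$p_e,
                 p_opt - 1e-12)
    }
  }
})

test_that("error probability decreases monotonically with mean separation", {
  p_e <- sapply(seq(0.5, 4, by = 0.5), function(d) {
    pr <- decision_problem(gaussian_model(0, 1), gaussian_model(d, 1))
    closed_form_errors(pr)$p_e
  })
  expect_true(all(diff(p_e) < 0))
})

test_that("symmetric problems satisfy P_FA = P_M = Q(d / 2 sigma) exactly", {
  set.seed(91)
  for (rep in 1:10) {
    d <- runif(1, 0.2, 4); sigma <- runif(1, 0.3, 2); mu0 <- runif(1, -2, 2)
    pr <- decision_problem(gaussian_model(mu0, sigma^2),
                           gaussian_model(mu0 + d, sigma^2))
    r <- closed_form_errors(pr)
    expect_equal(r$p_fa, q_function(d / (2 * sigma)), tolerance = 1e-9)
    expect_equal(r$p_m, q_function(d / (2 * sigma)), tolerance = 1e-9)
  }
})
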