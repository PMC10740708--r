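test_that("equal-variance problems give the midpoint threshold", {
  pr <- decision_problem(gaussian_model(0, 1), gaussian_model(2, 1))
  b <- solve_univariate_threshold(pr)
  expect_equal(b$roots, 1)
  expect_equal(b$intervals$decision, c("H0", "H1"))
})

test_that("unequal variances give two symmetric roots with H1 in the tails", {
  pr <- decision_problem(gaussian_model(0, 1), gaussian_model(0, 4))
  b <- solve_univariate_threshold(pr)
  xth <- sqrt((8 / 3) * log(2))  # closed form for this configuration
  expect_equal(b$roots, c(-xth, xth), tolerance = 1e-12)
  expect_equal(b$intervals$decision, c("H1", "H0", "H1"))
  # density equality at each root (the defining property of the boundary)
  for (r in b$roots) {
    expect_equal(exp(log_pdf(pr$h1, r)), exp(log_pdf(pr$h0, r)), tolerance = 1e-10)
  }
})

test_that("general priors shift the constant term of the quadratic", {
  # mu0=0, mu1=2, sigma=1: ln L(x) = 2x - 2, boundary at x = (2 + ln gamma)/2
  pr <- decision_problem(gaussian_model(0, 1), gaussian_model(2, 1),
                         prior0 = exp(1) / (1 + exp(1)))  # gamma = e
  b <- solve_univariate_threshold(pr)
  expect_equal(b$roots, 1.5, tolerance = 1e-12)
})

test_that("boundary points satisfy weighted-density equality for random problems", {
  set.seed(77)
  for (rep in 1:20) {
    pr <- random_problem_1d()
    b <- solve_univariate_threshold(pr)
    for (r in b$roots) {
      w1 <- exp(log_pdf(pr$h1, r)) * pr$prior1
      w0 <- exp(log_pdf(pr$h0, r)) * pr$prior0
      expect_lt(abs(w1 - w0), 1e-8 * max(w0, w1, 1e-300))
    }
    # side decisions consistent with the sign of ln L - ln gamma at midpoints
    iv <- b$intervals
    mids <- ifelse(is.infinite(iv$lower) & is.infinite(iv$upper), 0,
                   ifelse(is.infinite(iv$lower), iv$upper - 1,
                          ifelse(is.infinite(iv$upper), iv$lower + 1,
                                 (iv$lower + iv$upper) / 2)))
    lr <- log_likelihood_ratio(pr, matrix(mids, ncol = 1)) - pr$log_gamma
    expect_equal(iv$decision, ifelse(lr > 0, "H1", "H0"))
  }
})

test_that("dominated and degenerate univariate problems return boundary-free results", {
  same <- decision_problem(gaussian_model(1, 2), gaussian_model(1, 2))
  expect_warning(b <- solve_univariate_threshold(same), "identical models")
  expect_length(b$roots, 0)
  expect_equal(b$dominant, "H0")  # tie decides H0

  # equal means/variances but unequal priors: H0 (gamma > 1) dominates
  pr <- decision_problem(gaussian_model(1, 2), gaussian_model(1, 2), prior0 = 0.8)
  b2 <- solve_univariate_threshold(pr)
  expect_length(b2$roots, 0)
  expect_equal(b2$dominant, "H0")
})

test_that("equal-covariance 2-D problems yield a straight-line DTC", {
  pr <- decision_problem(gaussian_model(c(0, 0), diag(2)),
                         gaussian_model(c(2, 0), diag(2)))
  d <- trace_dtc(pr, resolution = 256)
  expect_equal(d$conic, "line")
  xs <- unlist(lapply(d$curves, function(cc) cc$x))
  expect_gt(length(xs), 50)
  expect_lt(max(abs(xs - 1)), 1e-6)
})

test_that("concentric covariance-scaled Gaussians yield the closed-form circle", {
  pr <- decision_problem(gaussian_model(c(0, 0), diag(2)),
                         gaussian_model(c(0, 0), 4 * diag(2)))
  d <- trace_dtc(pr)
  expect_equal(d$conic, "ellipse")
  r_true <- sqrt((8 / 3) * log(4))  # solve (3/8) r^2 = ln 4 analytically
  r <- sqrt(unlist(lapply(d$curves, function(cc) cc$x^2 + cc$y^2)))
  expect_lt(max(abs(r - r_true)), 1e-4)
  # ln L = 0 on every polished vertex
  expect_lt(d$max_residual, 1e-9)
})

test_that("DTC vertices satisfy |ln L - ln gamma| <= tol for random problems", {
  set.seed(88)
  for (rep in 1:8) {
    pr <- random_problem_2d(equal_priors = FALSE)
    d <- trace_dtc(pr, resolution = 256)
    if (length(d$curves) == 0) {
      expect_true(d$dominant %in% c("H0", "H1"))
      next
    }
    for (cc in d$curves) {
      resid <- abs(log_likelihood_ratio(pr, cbind(cc$x, cc$y)) - pr$log_gamma)
      expect_lt(max(resid), 1e-9)
    }
  }
})

test_that("the bivariate quadratic reduces to the univariate one", {
  # embed a 1-D problem with an independent, identical y-marginal: the DTC
  # must be the vertical lines at the univariate roots
  pr1 <- decision_problem(gaussian_model(0, 1), gaussian_model(0.5, 4))
  b1 <- solve_univariate_threshold(pr1)
  expect_length(b1$roots, 2)
  pr2 <- decision_problem(
    gaussian_model(c(0, 1), diag(c(1, 0.7))),
    gaussian_model(c(0.5, 1), diag(c(4, 0.7))))
  d <- trace_dtc(pr2)
  for (cc in d$curves) {
    dist_to_roots <- vapply(cc$x, function(x) min(abs(x - b1$roots)), numeric(1))
    expect_lt(max(dist_to_roots), 1e-6)
  }
})

test_that("conic classification agrees with the sign pattern of the quadratic", {
  # hyperbola: opposite-sign curvature plus a mean shift (nondegenerate conic)
  pr <- decision_problem(gaussian_model(c(0, 0), diag(c(1, 2))),
                         gaussian_model(c(1, 0), diag(c(2, 1))))
  expect_equal(trace_dtc(pr, resolution = 128)$conic, "hyperbola")
  # crossing-lines case (same means): quadratic part indefinite, conic singular
  prx <- decision_problem(gaussian_model(c(0, 0), diag(c(1, 2))),
                          gaussian_model(c(0, 0), diag(c(2, 1))))
  expect_equal(trace_dtc(prx, resolution = 128)$conic, "degenerate")
  # identical models: degenerate, boundary-free with warning
  same <- decision_problem(gaussian_model(c(0, 0), diag(2)),
                           gaussian_model(c(0, 0), diag(2)))
  expect_warning(d <- trace_dtc(same, resolution = 64), "identical models")
  expect_length(d$curves, 0)
})
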