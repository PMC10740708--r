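#' Gaussian upper-tail probability (Q function)
#'
#' \eqn{Q(\eta) = (2\pi)^{-1/2} \int_\eta^\infty e^{-u^2/2}\,du}, the
#' standard-normal upper-tail probability, computed via the complementary
#' error function to full double precision.
#'
#' @param eta numeric vector.
#' @return `P(U > eta)` for a standard normal U.
#' @export
q_function <- function(eta) {
  stats::pnorm(eta, lower.tail = FALSE)
}

#' Overall decision error probability
#'
#' The prior-weighted combination of the false-alarm and miss probabilities,
#' `P_E = P(H0) * P_FA + P(H1) * P_M`, which the optimal likelihood-ratio
#' rule minimizes.
#'
#' @param p_fa false-alarm probability P(decide H1 | H0).
#' @param p_m miss probability P(decide H0 | H1).
#' @param prior0,prior1 prior probabilities; must sum to 1.
#' @return The overall error probability.
#' @export
overall_error <- function(p_fa, p_m, prior0 = 0.5, prior1 = 1 - prior0) {
  if (any(c(p_fa, p_m, prior0, prior1) < 0) || any(c(p_fa, p_m, prior0, prior1) > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  if (abs(prior0 + prior1 - 1) > 1e-12) stop("priors must sum to 1")
  prior0 * p_fa + prior1 * p_m
}

error_report <- function(p_fa, p_m, problem, method,
                         n_samples = NA_integer_, mc_stderr = NULL,
                         seed = NA_integer_) {
  structure(list(p_fa = p_fa, p_m = p_m,
                 p_e = overall_error(p_fa, p_m, problem$prior0, problem$prior1),
                 prior0 = problem$prior0, prior1 = problem$prior1,
                 method = method, n_samples = n_samples,
                 mc_stderr = mc_stderr, seed = seed),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("<error_report> method %s: P_FA = %.4g, P_M = %.4g, P_E = %.4g\n",
              x$method, x$p_fa, x$p_m, x$p_e))
  if (!is.na(x$n_samples)) cat(sprintf("  n = %d per hypothesis\n", x$n_samples))
  if (!is.null(x$mc_stderr)) {
    cat(sprintf("  binomial stderr: P_FA %.2g, P_M %.2g (seed %d)\n",
                x$mc_stderr["p_fa"], x$mc_stderr["p_m"], x$seed))
  }
  invisible(x)
}

#' Closed-form error probabilities for a univariate problem
#'
#' Integrates each class density over the opposing decision region using the
#' Q function. With a single threshold this is `P_FA = Q((x_th - mu0)/sigma0)`
#' and `P_M = Q((mu1 - x_th)/sigma1)`; with two roots (unequal variances) the
#' Gaussian probabilities of the H1-decided intervals are summed under the H0
#' density (and conversely for the miss). A boundary-free problem yields
#' degenerate probabilities 0/1 according to the dominant hypothesis.
#'
#' @param problem a one-dimensional [decision_problem()].
#' @param boundary result of [solve_univariate_threshold()]; computed if
#'   omitted.
#' @return An `error_report` with `method = "closed_form"`.
#' @export
closed_form_errors <- function(problem,
                               boundary = solve_univariate_threshold(problem)) {
  if (problem$dim != 1L || boundary$dim != 1L) {
    stop("closed-form integration requires a one-dimensional problem")
  }
  iv <- boundary$intervals
  mass <- function(model, lower, upper) {
    mu <- model$mu[1]; sd <- sqrt(model$sigma[1, 1])
    stats::pnorm(upper, mu, sd) - stats::pnorm(lower, mu, sd)
  }
  h1_iv <- iv[iv$decision == "H1", , drop = FALSE]
  h0_iv <- iv[iv$decision == "H0", , drop = FALSE]
  p_fa <- if (nrow(h1_iv)) sum(mass(problem$h0, h1_iv$lower, h1_iv$upper)) else 0
  p_m <- if (nrow(h0_iv)) sum(mass(problem$h1, h0_iv$lower, h0_iv$upper)) else 0
  error_report(min(max(p_fa, 0), 1), min(max(p_m, 0), 1), problem, "closed_form")
}

#' Monte Carlo error probabilities by region integration
#'
#' Estimates the false-alarm probability as the fraction of draws from
#' p(z|H0) falling in the H1-decision region (ln L > ln gamma), and the miss
#' probability as the fraction of draws from p(z|H1) falling in the
#' H0-decision region (ln L <= ln gamma; ties decide H0). Works for any
#' dimension. Binomial standard errors `sqrt(p(1-p)/n)` are reported, and the
#' seed is recorded so the draws can be reproduced: the generator state is set
#' with `set.seed(seed)`, then `n` points are drawn from H0, then `n` from H1
#' (see [sample_gaussian()]).
#'
#' @param problem a [decision_problem()].
#' @param n draws per hypothesis (>= 1000).
#' @param seed integer seed (mandatory, recorded in the report).
#' @return An `error_report` with `method = "monte_carlo"`.
#' @export
monte_carlo_errors <- function(problem, n = 1e6, seed) {
  if (missing(seed)) stop("a seed must be supplied and is recorded in the report")
  n <- as.integer(n)
  if (n < 1000L) stop("n must be at least 1000")
  set.seed(seed)
  z0 <- sample_gaussian(problem$h0, n)
  z1 <- sample_gaussian(problem$h1, n)
  p_fa <- mean(log_likelihood_ratio(problem, z0) > problem$log_gamma)
  p_m <- mean(log_likelihood_ratio(problem, z1) <= problem$log_gamma)
  se <- c(p_fa = sqrt(p_fa * (1 - p_fa) / n), p_m = sqrt(p_m * (1 - p_m) / n))
  error_report(p_fa, p_m, problem, "monte_carlo",
               n_samples = n, mc_stderr = se, seed = as.integer(seed))
}

#' Empirical error probabilities by discriminant-function counting
#'
#' For each observed point the discriminant functions
#' `g_i(z) = ln p(z|H_i) + ln P(H_i)` are compared. A false alarm is counted
#' whenever `g_1(z) > g_0(z)` for a point observed under H0, and P_FA is that
#' count divided by the number of H0 points; P_M is computed symmetrically
#' from the H1 points (`g_1 <= g_0`, so a tie decides H0). Since
#' `g_1(z) > g_0(z)` is equivalent to `ln L(z) > ln gamma` (the shared
#' normalizing terms cancel), this estimator applied to model-drawn samples
#' coincides draw-for-draw with [monte_carlo_errors()].
#'
#' @param problem a [decision_problem()].
#' @param data0 matrix of points observed under H0 (rows).
#' @param data1 matrix of points observed under H1 (rows).
#' @return An `error_report` with `method = "empirical_count"`.
#' @export
empirical_count_errors <- function(problem, data0, data1) {
  data0 <- as_points(data0, problem$dim)
  data1 <- as_points(data1, problem$dim)
  if (nrow(data0) == 0L || nrow(data1) == 0L) {
    stop("data0 and data1 must be nonempty")
  }
  g <- function(model, prior, z) log_pdf(model, z) + log(prior)
  d0_fa <- g(problem$h1, problem$prior1, data0) > g(problem$h0, problem$prior0, data0)
  d1_miss <- g(problem$h1, problem$prior1, data1) <= g(problem$h0, problem$prior0, data1)
  # g1 > g0  <=>  ln L > ln gamma; check the identity on a subsample
  idx <- seq_len(min(32L, nrow(data0)))
  lr <- log_likelihood_ratio(problem, data0[idx, , drop = FALSE]) - problem$log_gamma
  stopifnot(all(d0_fa[idx] == (lr > 0) | abs(lr) < 1e-10))
  error_report(mean(d0_fa), mean(d1_miss), problem, "empirical_count",
               n_samples = nrow(data0))
}
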