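# Shared fixtures: all built in code at test time.

# random PD covariance in 2-D with bounded conditioning
random_cov2 <- function() {
  sd <- runif(2, 0.3, 2)
  rho <- runif(1, -0.8, 0.8)
  matrix(c(sd[1]^2, rho * prod(sd), rho * prod(sd), sd[2]^2), 2, 2)
}

random_problem_1d <- function() {
  decision_problem(gaussian_model(runif(1, -2, 2), runif(1, 0.2, 2)^2),
                   gaussian_model(runif(1, -2, 2), runif(1, 0.2, 2)^2),
                   prior0 = runif(1, 0.2, 0.8))
}

random_problem_2d <- function(equal_priors = TRUE) {
  decision_problem(gaussian_model(runif(2, -2, 2), random_cov2()),
                   gaussian_model(runif(2, -2, 2), random_cov2()),
                   prior0 = if (equal_priors) 0.5 else runif(1, 0.2, 0.8))
}

# small synthetic table with two output columns
tiny_table <- function(n = 30, seed = 11) {
  set.seed(seed)
  cell_table(condition_id = rep(c("lo", "hi"), each = n),
             input_level = rep(c(0.013, 3.2), each = n),
             timepoint = 30,
             outputs = data.frame(NFkB = exp(rnorm(2 * n, 5, 0.5)),
                                  ATF2 = exp(rnorm(2 * n, 5, 0.5))))
}

# rigid shift of a 1-D boundary: move every root/breakpoint by delta,
# keeping the per-interval decisions (a deliberately suboptimal rule)
shift_boundary <- function(b, delta) {
  stopifnot(b$dim == 1L, length(b$roots) > 0L)
  b$roots <- b$roots + delta
  brk <- c(-Inf, b$roots, Inf)
  b$intervals$lower <- brk[-length(brk)]
  b$intervals$upper <- brk[-1]
  b
}

# standard-normal upper tail by adaptive quadrature (oracle, independent of
# the pnorm-based implementation path)
quad_tail <- function(eta) {
  stats::integrate(function(u) exp(-u^2 / 2) / sqrt(2 * pi), eta, Inf,
                   rel.tol = 1e-12)$value
}
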