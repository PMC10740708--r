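#' Construct a Gaussian model of log-concentrations
#'
#' The observation model for one hypothesis: an N-variate Gaussian density
#' \deqn{p(z \mid H_i) = (2\pi)^{-N/2} |\Sigma_i|^{-1/2}
#'   \exp\{-\tfrac12 (z-\mu_i)^T \Sigma_i^{-1} (z-\mu_i)\}}
#' over the vector of log-transformed output concentrations.
#'
#' @param mu numeric mean vector (log-concentration units).
#' @param sigma covariance matrix; a scalar is taken as a 1x1 variance.
#' @return A `gaussian_model` with fields `dim`, `mu`, `sigma` and the derived
#'   quantities `chol` (upper Cholesky factor), `log_det`, `inv`, and for
#'   two-dimensional models the correlation `rho`.
#' @export
gaussian_model <- function(mu, sigma) {
  mu <- as.numeric(mu)
  n <- length(mu)
  sigma <- as.matrix(sigma)
  if (!all(dim(sigma) == c(n, n))) stop("sigma must be ", n, "x", n)
  if (max(abs(sigma - t(sigma))) > 1e-8 * max(1, max(abs(sigma)))) {
    stop("sigma must be symmetric")
  }
  sigma <- (sigma + t(sigma)) / 2
  R <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(R) || kappa(sigma, exact = TRUE) > 1e12) {
    stop("degenerate model: covariance is singular or ill-conditioned",
         call. = FALSE)
  }
  rho <- if (n == 2L) sigma[1, 2] / sqrt(sigma[1, 1] * sigma[2, 2]) else NULL
  structure(list(dim = n, mu = mu, sigma = sigma,
                 chol = R,
                 log_det = 2 * sum(log(diag(R))),
                 inv = chol2inv(R),
                 rho = rho),
            class = "gaussian_model")
}

#' @export
print.gaussian_model <- function(x, ...) {
  cat(sprintf("<gaussian_model> dim %d\n  mu: %s\n", x$dim,
              paste(signif(x$mu, 5), collapse = ", ")))
  cat("  sigma:\n")
  print(signif(x$sigma, 5))
  invisible(x)
}

#' Fit a Gaussian model to log-concentration samples
#'
#' Estimates the mean vector as the sample mean and the covariance with the
#' unbiased (n - 1) denominator, then verifies positive definiteness. A
#' constant column (zero variance) or near-singular covariance raises a
#' degenerate-model error naming the offending output.
#'
#' @param samples numeric matrix, n cells by N outputs (a vector is taken as
#'   a one-output sample).
#' @return A [gaussian_model()].
#' @export
fit_gaussian <- function(samples) {
  samples <- as.matrix(samples)
  n <- nrow(samples)
  d <- ncol(samples)
  if (anyNA(samples)) stop("samples contain missing values")
  if (n < d + 1L) stop("need at least N+1 = ", d + 1L, " samples, got ", n)
  mu <- colMeans(samples)
  sigma <- stats::cov(samples)
  vars <- diag(as.matrix(sigma))
  if (any(vars <= 0)) {
    cols <- colnames(samples)
    if (is.null(cols)) cols <- paste0("output", seq_len(d))
    stop("degenerate model: zero variance in output(s): ",
         paste(cols[vars <= 0], collapse = ", "), call. = FALSE)
  }
  gaussian_model(mu, sigma)
}

#' Evaluate the log-density of a Gaussian model
#'
#' Computed directly in log form (never exp-then-log) via the Cholesky factor,
#' so it is numerically stable far into the tails.
#'
#' @param model a [gaussian_model()].
#' @param z a numeric vector of length `model$dim`, or a matrix with one point
#'   per row.
#' @return Numeric vector of log-density values, one per point.
#' @export
log_pdf <- function(model, z) {
  z <- as_points(z, model$dim)
  centered <- sweep(z, 2L, model$mu)
  # whitened coordinates: solve R^T u = (z - mu)^T  =>  quad form = |u|^2
  u <- backsolve(model$chol, t(centered), transpose = TRUE)
  quad <- colSums(u^2)
  -0.5 * (model$dim * log(2 * pi) + model$log_det + quad)
}

as_points <- function(z, dim) {
  if (is.null(dim(z))) {
    if (length(z) %% dim != 0L || (dim > 1L && length(z) != dim)) {
      if (dim == 1L) z <- matrix(z, ncol = 1L)
      else stop("point dimension ", length(z), " does not match model dim ", dim)
    } else {
      z <- matrix(z, ncol = dim, byrow = TRUE)
    }
  } else {
    z <- as.matrix(z)
  }
  if (ncol(z) != dim) {
    stop("point dimension ", ncol(z), " does not match model dim ", dim)
  }
  z
}

#' Draw samples from a Gaussian model
#'
#' Uses the upper Cholesky factor of the covariance; with a fixed RNG state
#' the draws are reproducible, which lets the Monte Carlo and
#' discriminant-counting error estimators share samples draw-for-draw.
#'
#' @param model a [gaussian_model()].
#' @param n number of points.
#' @return n-by-dim numeric matrix.
#' @export
sample_gaussian <- function(model, n) {
  z <- matrix(stats::rnorm(n * model$dim), nrow = n) %*% model$chol
  sweep(z, 2L, model$mu, `+`)
}

#' Define a binary decision problem
#'
#' Pairs the Gaussian observation models under the "input low" (H0) and
#' "input high" (H1) hypotheses with their prior probabilities. The optimal
#' (minimum overall error) rule compares the likelihood ratio
#' L(z) = p(z|H1)/p(z|H0) against the threshold gamma = P(H0)/P(H1) and
#' decides H1 when L(z) > gamma.
#'
#' @param h0,h1 [gaussian_model()]s of equal dimension.
#' @param prior0 prior probability of H0, strictly in (0, 1); equal priors by
#'   default.
#' @param prior1 prior probability of H1; defaults to `1 - prior0`.
#' @return A `decision_problem` with fields `h0`, `h1`, `prior0`, `prior1`,
#'   `gamma`, `log_gamma`, `dim`.
#' @export
decision_problem <- function(h0, h1, prior0 = 0.5, prior1 = 1 - prior0) {
  stopifnot(inherits(h0, "gaussian_model"), inherits(h1, "gaussian_model"))
  if (h0$dim != h1$dim) stop("h0 and h1 must have equal dimension")
  if (abs(prior0 + prior1 - 1) > 1e-12) stop("priors must sum to 1")
  if (prior0 <= 0 || prior0 >= 1) stop("priors must be strictly in (0, 1)")
  structure(list(h0 = h0, h1 = h1, prior0 = prior0, prior1 = prior1,
                 gamma = prior0 / prior1,
                 log_gamma = log(prior0) - log(prior1),
                 dim = h0$dim),
            class = "decision_problem")
}

#' @export
print.decision_problem <- function(x, ...) {
  cat(sprintf("<decision_problem> dim %d, P(H0) = %g, gamma = %g\n",
              x$dim, x$prior0, x$gamma))
  invisible(x)
}

#' Log-likelihood ratio of a decision problem
#'
#' Returns ln L(z) = ln p(z|H1) - ln p(z|H0). The optimal rule decides H1
#' where ln L(z) > ln gamma; a tie (ln L = ln gamma exactly) decides H0, a
#' convention applied consistently by every estimator in the package.
#'
#' @param problem a [decision_problem()].
#' @param z point or matrix of points (rows).
#' @return Numeric vector of ln L values.
#' @export
log_likelihood_ratio <- function(problem, z) {
  log_pdf(problem$h1, z) - log_pdf(problem$h0, z)
}

#' Decide between hypotheses for observed points
#'
#' @param problem a [decision_problem()].
#' @param z point or matrix of points.
#' @return Integer vector: 1 where H1 is decided (ln L > ln gamma), else 0.
#' @export
decide <- function(problem, z) {
  as.integer(log_likelihood_ratio(problem, z) > problem$log_gamma)
}
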