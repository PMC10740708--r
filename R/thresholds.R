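#' @rdname solve_univariate_threshold
#' @param x a `decision_boundary`.
#' @param ... unused.
#' @export
print.decision_boundary <- function(x, ...) {
  if (x$dim == 1L) {
    if (length(x$roots) == 0L) {
      cat(sprintf("<decision_boundary> dim 1, boundary-free (%s dominates)\n",
                  x$dominant))
    } else {
      cat(sprintf("<decision_boundary> dim 1, root(s): %s\n",
                  paste(signif(x$roots, 6), collapse = ", ")))
      print(x$intervals)
    }
  } else {
    if (is.null(x$curves) || length(x$curves) == 0L) {
      cat(sprintf("<decision_boundary> dim 2, boundary-free (%s dominates)\n",
                  x$dominant))
    } else {
      cat(sprintf("<decision_boundary> dim 2, conic type '%s', %d polyline(s), %d vertices\n",
                  x$conic, length(x$curves),
                  sum(vapply(x$curves, nrow, integer(1)))))
    }
  }
  invisible(x)
}

# Coefficients of the quadratic q(x) = a x^2 + b x + c whose zero set is the
# optimal 1-D threshold set; ln L(x) - ln gamma = -q(x)/2, so H1 is decided
# where q(x) < 0. With equal priors (gamma = 1) this is the classical
# unequal-variance threshold quadratic; general priors add 2 ln gamma to the
# constant term.
univariate_quadratic <- function(problem) {
  m0 <- problem$h0; m1 <- problem$h1
  v0 <- m0$sigma[1, 1]; v1 <- m1$sigma[1, 1]
  mu0 <- m0$mu[1]; mu1 <- m1$mu[1]
  list(a = 1 / v1 - 1 / v0,
       b = -2 * (mu1 / v1 - mu0 / v0),
       c = mu1^2 / v1 - mu0^2 / v0 + log(v1 / v0) + 2 * problem$log_gamma)
}

#' Solve the optimal univariate decision threshold
#'
#' The boundary points where the prior-weighted class densities are equal,
#' i.e. where ln L(x) = ln gamma, are the real roots of a quadratic in x
#' (linear when the two variances are equal, giving the familiar midpoint
#' threshold). Unequal variances generically give two roots; both are
#' returned, with the winning hypothesis on every interval between them. When
#' no real root exists, one hypothesis dominates the whole line and a
#' boundary-free result is returned rather than an error.
#'
#' @param problem a one-dimensional [decision_problem()].
#' @return A `decision_boundary` with fields `dim = 1`, `roots` (sorted),
#'   `intervals` (data frame of `lower`, `upper`, `decision`), and `dominant`
#'   (`NA`, or the hypothesis deciding everywhere when `roots` is empty).
#' @export
solve_univariate_threshold <- function(problem) {
  if (problem$dim != 1L) stop("problem must be one-dimensional")
  q <- univariate_quadratic(problem)
  scale_a <- max(1 / problem$h0$sigma[1, 1], 1 / problem$h1$sigma[1, 1])
  roots <- numeric(0)
  if (abs(q$a) < 1e-12 * scale_a) {
    if (abs(q$b) < 1e-12 * scale_a * max(1, abs(problem$h0$mu[1]), abs(problem$h1$mu[1]))) {
      # identical first and second moments: ln L is constant
      dominant <- if (-q$c / 2 > 0) "H1" else "H0"
      if (abs(q$c) < 1e-12) {
        warning("identical models: likelihood ratio is 1 everywhere; boundary undefined")
      }
      return(univariate_boundary(roots, dominant, problem))
    }
    roots <- -q$c / q$b
  } else {
    disc <- q$b^2 - 4 * q$a * q$c
    if (disc < 0) {
      # q(x) keeps the sign of a: H1 decided where q < 0
      dominant <- if (q$a < 0) "H1" else "H0"
      return(univariate_boundary(roots, dominant, problem))
    }
    # numerically stable quadratic formula
    sq <- sqrt(disc)
    t <- -(q$b + sign(q$b + (q$b == 0)) * sq) / 2
    roots <- if (sq == 0) t / q$a else sort(c(t / q$a, q$c / t))
  }
  univariate_boundary(sort(roots), NA_character_, problem)
}

univariate_boundary <- function(roots, dominant, problem) {
  if (length(roots) == 0L) {
    intervals <- data.frame(lower = -Inf, upper = Inf, decision = dominant,
                            stringsAsFactors = FALSE)
  } else {
    brk <- c(-Inf, roots, Inf)
    lower <- brk[-length(brk)]
    upper <- brk[-1]
    mids <- ifelse(is.infinite(lower), upper - 1,
                   ifelse(is.infinite(upper), lower + 1, (lower + upper) / 2))
    lr <- log_likelihood_ratio(problem, matrix(mids, ncol = 1)) - problem$log_gamma
    decision <- ifelse(lr > 0, "H1", "H0")  # tie -> H0
    intervals <- data.frame(lower = lower, upper = upper, decision = decision,
                            stringsAsFactors = FALSE)
  }
  structure(list(dim = 1L, roots = roots, intervals = intervals,
                 dominant = dominant),
            class = "decision_boundary")
}

#' Trace the optimal decision threshold curve (DTC)
#'
#' For a two-output problem the set where the prior-weighted class densities
#' are equal, \{z : ln L(z) = ln gamma\}, is a conic section (the zero set of
#' a bivariate quadratic). The curve is extracted numerically: ln L - ln gamma
#' is evaluated on a regular grid over the bounding box, the zero-level
#' contour is traced by marching squares, and every vertex is refined by
#' bisection along its grid edge until |ln L - ln gamma| is below `tol_curve`.
#' The conic type is classified from the quadratic-form coefficients.
#'
#' @param problem a two-dimensional [decision_problem()].
#' @param bbox numeric vector `c(xmin, xmax, ymin, ymax)`; defaults to the
#'   union of the two per-model boxes mu +/- 5 marginal SDs (covering
#'   essentially all of each density's mass).
#' @param resolution grid points per axis (default 512).
#' @param tol_curve target |ln L - ln gamma| at polished vertices.
#' @return A `decision_boundary` with `dim = 2`, `curves` (list of data frames
#'   with columns `x`, `y`), `conic` (one of `"line"`, `"ellipse"`,
#'   `"parabola"`, `"hyperbola"`, `"parallel lines"`, `"degenerate"`), `bbox`,
#'   `max_residual`, and `dominant` when the likelihood ratio has constant
#'   sign on the box (boundary-free).
#' @export
trace_dtc <- function(problem, bbox = NULL, resolution = 512L,
                      tol_curve = 1e-9) {
  if (problem$dim != 2L) stop("problem must be two-dimensional")
  if (is.null(bbox)) bbox <- default_bbox(problem)
  gx <- seq(bbox[1], bbox[2], length.out = resolution)
  gy <- seq(bbox[3], bbox[4], length.out = resolution)
  pts <- cbind(rep(gx, times = resolution), rep(gy, each = resolution))
  f_val <- log_likelihood_ratio(problem, pts) - problem$log_gamma
  fmat <- matrix(f_val, nrow = resolution)  # fmat[i, j] = F(gx[i], gy[j])

  conic <- classify_conic(problem)
  if (all(f_val > 0) || all(f_val <= 0)) {
    dominant <- if (all(f_val > 0)) "H1" else "H0"
    if (conic == "degenerate" && max(abs(f_val)) < 1e-9) {
      warning("identical models: likelihood ratio is 1 everywhere; boundary undefined")
    }
    return(structure(list(dim = 2L, curves = list(), conic = conic,
                          bbox = bbox, dominant = dominant,
                          max_residual = NA_real_),
                     class = "decision_boundary"))
  }

  f_fun <- function(x, y) {
    log_likelihood_ratio(problem, cbind(x, y)) - problem$log_gamma
  }
  cl <- grDevices::contourLines(gx, gy, fmat, levels = 0)
  curves <- lapply(cl, function(seg) {
    polish_contour(seg$x, seg$y, gx, gy, f_fun)
  })
  resid <- if (length(curves) > 0) {
    max(vapply(curves, function(cc) max(abs(f_fun(cc$x, cc$y))), numeric(1)))
  } else NA_real_
  if (is.finite(resid) && resid > tol_curve) {
    warning("DTC vertex residual ", signif(resid, 3),
            " exceeds tol_curve = ", tol_curve)
  }
  structure(list(dim = 2L, curves = curves, conic = conic, bbox = bbox,
                 dominant = NA_character_, max_residual = resid),
            class = "decision_boundary")
}

default_bbox <- function(problem, k = 5) {
  box <- function(m) {
    sd <- sqrt(diag(m$sigma))
    c(m$mu - k * sd, m$mu + k * sd)  # (xlo, ylo, xhi, yhi)
  }
  b0 <- box(problem$h0); b1 <- box(problem$h1)
  c(min(b0[1], b1[1]), max(b0[3], b1[3]),
    min(b0[2], b1[2]), max(b0[4], b1[4]))
}

# Marching-squares vertices sit on grid edges: x on a grid line (vertical
# edge, y interpolated) or y on a grid line (horizontal edge, x interpolated).
# Refine the interpolated coordinate by bisection within its bracketing cell.
polish_contour <- function(vx, vy, gx, gy, f_fun, iters = 80L) {
  nearest <- function(v, g) {
    i <- pmin(pmax(findInterval(v, g), 1L), length(g))
    i2 <- pmin(i + 1L, length(g))
    ifelse(abs(v - g[i]) <= abs(g[i2] - v), i, i2)
  }
  ix <- nearest(vx, gx); iy <- nearest(vy, gy)
  on_vert <- abs(vx - gx[ix]) <= abs(vy - gy[iy])  # x exact, polish y

  # bracketing interval along the free coordinate
  free <- ifelse(on_vert, vy, vx)
  grid_free <- function(i, on_v) ifelse(on_v, gy[pmin(i, length(gy))], gx[pmin(i, length(gx))])
  j <- ifelse(on_vert,
              pmin(pmax(findInterval(vy, gy), 1L), length(gy) - 1L),
              pmin(pmax(findInterval(vx, gx), 1L), length(gx) - 1L))
  lo <- grid_free(j, on_vert)
  hi <- grid_free(j + 1L, on_vert)
  fixed <- ifelse(on_vert, gx[ix], gy[iy])

  eval_at <- function(free_val) {
    x <- ifelse(on_vert, fixed, free_val)
    y <- ifelse(on_vert, free_val, fixed)
    f_fun(x, y)
  }
  flo <- eval_at(lo); fhi <- eval_at(hi)
  ok <- flo * fhi <= 0 & is.finite(flo) & is.finite(fhi)
  lo2 <- lo; hi2 <- hi
  for (k in seq_len(iters)) {
    mid <- (lo2 + hi2) / 2
    fm <- eval_at(mid)
    move_lo <- (fm * flo > 0)
    lo2 <- ifelse(ok & move_lo, mid, lo2)
    flo <- ifelse(ok & move_lo, fm, flo)
    hi2 <- ifelse(ok & !move_lo, mid, hi2)
  }
  root <- (lo2 + hi2) / 2
  free_out <- ifelse(ok, root, free)
  data.frame(x = ifelse(on_vert, fixed, free_out),
             y = ifelse(on_vert, free_out, fixed))
}

# Conic type of z^T M z + b^T z + c0 = 0 with M = S1inv - S0inv.
classify_conic <- function(problem) {
  m0 <- problem$h0; m1 <- problem$h1
  M <- m1$inv - m0$inv
  bv <- -2 * (m1$inv %*% m1$mu - m0$inv %*% m0$mu)
  c0 <- drop(t(m1$mu) %*% m1$inv %*% m1$mu - t(m0$mu) %*% m0$inv %*% m0$mu) +
    (m1$log_det - m0$log_det) + 2 * problem$log_gamma
  A <- M[1, 1]; B <- 2 * M[1, 2]; C <- M[2, 2]
  D <- bv[1]; E <- bv[2]
  scale <- max(abs(c(A, B, C, D, E, c0)), 1e-300)
  tol <- 1e-10 * scale
  if (max(abs(c(A, B, C))) < tol) {
    if (max(abs(c(D, E))) < tol) return("degenerate")
    return("line")
  }
  disc <- B^2 - 4 * A * C
  det3 <- det(matrix(c(A, B / 2, D / 2,
                       B / 2, C, E / 2,
                       D / 2, E / 2, c0), 3, 3))
  if (abs(det3) < 1e-10 * scale^3) {
    if (abs(disc) < tol^2) return("parallel lines")
    return("degenerate")
  }
  if (disc < -tol^2) "ellipse" else if (disc > tol^2) "hyperbola" else "parabola"
}
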