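#' Lorentzian inner product
#'
#' Bilinear form of the ambient Lorentzian space R^{d,1}:
#' \code{sum(x[1:d] * y[1:d]) - x[d+1] * y[d+1]}.  The last ("time-like")
#' coordinate carries the negative sign.  Between two points of the upper
#' hyperboloid sheet the form is always <= -1.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return a single numeric value.
#' @examples
#' lorentz_inner(c(0, 0, 1), c(0, 0, 1))  # -1 at the vertex
#' @export
lorentz_inner <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("lorentz_inner: vectors must have equal length >= 2")
  n <- length(x)
  sum(x[-n] * y[-n]) - x[n] * y[n]
}

## Row-wise Lorentzian Gram matrix: <U_i, V_j>_L for all pairs.
## U: m x (d+1), V: n x (d+1).  Used by all vectorized paths.
lorentz_gram <- function(U, V) {
  k <- ncol(U)
  Vflip <- V
  Vflip[, k] <- -Vflip[, k]
  U %*% t(Vflip)
}

#' Check the hyperboloid constraint
#'
#' A point of the Lorentz model satisfies \code{lorentz_inner(x, x) == -1}
#' with positive last coordinate (upper sheet, so \code{x[d+1] >= 1}).
#'
#' @param x numeric vector, or a matrix whose rows are points.
#' @param tol absolute tolerance on the constraint residual.
#' @return logical.
#' @export
is_hyperboloid_point <- function(x, tol = 1e-9) {
  if (is.matrix(x)) return(all(apply(x, 1L, is_hyperboloid_point, tol = tol)))
  abs(lorentz_inner(x, x) + 1) <= tol && x[length(x)] > 0
}

assert_on_hyperboloid <- function(x, tol = 1e-6, what = "point") {
  ok <- if (is.matrix(x)) {
    n <- ncol(x)
    q <- rowSums(x[, -n, drop = FALSE]^2) - x[, n]^2
    all(abs(q + 1) <= tol) && all(x[, n] > 0)
  } else is_hyperboloid_point(x, tol)
  if (!ok) stop(sprintf("%s is not on the upper hyperboloid sheet (tolerance %g)",
                        what, tol))
  invisible(TRUE)
}

#' Hyperbolic (geodesic) distance on the hyperboloid
#'
#' \code{acosh(-lorentz_inner(x, y))}; the argument is clamped to be at
#' least 1 so that coincident points (whose inner product can land a hair
#' above -1 in floating point) return exactly 0.
#'
#' @param x,y points on the hyperboloid.
#' @param check validate the hyperboloid constraint first.
#' @return nonnegative distance.
#' @export
hyperbolic_distance <- function(x, y, check = TRUE) {
  if (check) { assert_on_hyperboloid(x, what = "x"); assert_on_hyperboloid(y, what = "y") }
  acosh(max(-lorentz_inner(x, y), 1))
}

#' Squared Lorentzian distance
#'
#' \code{-2 - 2 * lorentz_inner(x, y)}, equal to
#' \code{2 * (cosh(hyperbolic_distance(x, y)) - 1)} on the hyperboloid.
#' A monotone surrogate of the geodesic distance; it is what the logistic
#' link of the factorization model consumes.
#'
#' @inheritParams hyperbolic_distance
#' @return nonnegative value, 0 iff \code{x == y}.
#' @export
sq_lorentz_distance <- function(x, y, check = TRUE) {
  if (check) { assert_on_hyperboloid(x, what = "x"); assert_on_hyperboloid(y, what = "y") }
  max(-2 - 2 * lorentz_inner(x, y), 0)
}

## Lorentzian norm of a tangent vector (the form is positive definite
## on tangent spaces, so the square root is real).
lorentz_norm <- function(v) {
  q <- lorentz_inner(v, v)
  sqrt(max(q, 0))
}

#' Exponential map on the hyperboloid
#'
#' Shoots a tangent vector \code{y} at \code{mu} along its geodesic:
#' \code{cosh(|y|) * mu + sinh(|y|) * y / |y|} with the Lorentzian norm
#' \code{|y|}.  The geodesic length from \code{mu} to the image equals
#' \code{|y|}.  Norms below \code{1e-6} use the series limit
#' \code{sinh(t)/t = 1 + t^2/6 + t^4/120}, so the zero vector maps to
#' \code{mu} without a 0/0.
#'
#' @param mu base point on the hyperboloid.
#' @param y tangent vector at \code{mu} (Lorentz-orthogonal to it).
#' @param check validate tangency and the constraint.
#' @return a point on the hyperboloid.
#' @export
exp_map <- function(mu, y, check = TRUE) {
  if (check) {
    assert_on_hyperboloid(mu, what = "mu")
    if (abs(lorentz_inner(mu, y)) > 1e-6)
      stop("exp_map: y is not tangent at mu")
  }
  t <- lorentz_norm(y)
  if (t < 1e-6) {
    out <- cosh(t) * mu + (1 + t^2 / 6 + t^4 / 120) * y
  } else {
    out <- cosh(t) * mu + (sinh(t) / t) * y
  }
  reproject_hyperboloid(out)
}

#' Logarithm map on the hyperboloid
#'
#' Inverse of \code{\link{exp_map}}: returns the tangent vector at
#' \code{mu} whose exponential is \code{x}.  Computed as
#' \code{r / sinh(r) * (x + <mu,x>_L mu)} with
#' \code{r = hyperbolic_distance(mu, x)}; at \code{x == mu} the zero
#' vector is returned (series limit, not an error).
#'
#' @param mu,x points on the hyperboloid.
#' @param check validate inputs.
#' @return tangent vector at \code{mu} with Lorentzian norm
#'   \code{hyperbolic_distance(mu, x)}.
#' @export
log_map <- function(mu, x, check = TRUE) {
  if (check) { assert_on_hyperboloid(mu, what = "mu"); assert_on_hyperboloid(x, what = "x") }
  ip <- lorentz_inner(mu, x)
  r <- acosh(max(-ip, 1))
  v <- x + ip * mu                       # ambient projection onto T_mu
  if (r < 1e-6) {
    v / (1 + r^2 / 6 + r^4 / 120)        # r/sinh(r) by series
  } else {
    (r / sinh(r)) * v
  }
}

#' Parallel transport from the hyperboloid vertex
#'
#' Transports a tangent vector \code{x} at the vertex
#' \code{mu0 = (0, ..., 0, 1)} along the geodesic to the tangent space at
#' \code{mu}:
#' \code{x + <mu + <mu0,mu>_L mu0, x>_L / (1 - <mu0,mu>_L) * (mu0 + mu)}.
#' A linear isometry between the two tangent spaces.  The denominator
#' \code{1 - <mu0,mu>_L >= 2} on the upper sheet, so it never vanishes.
#'
#' @param mu destination point on the hyperboloid.
#' @param x tangent vector at the vertex (last coordinate 0).
#' @param check validate inputs.
#' @return tangent vector at \code{mu}.
#' @export
parallel_transport <- function(mu, x, check = TRUE) {
  k <- length(mu)
  mu0 <- c(rep(0, k - 1L), 1)
  if (check) {
    assert_on_hyperboloid(mu, what = "mu")
    if (abs(lorentz_inner(mu0, x)) > 1e-6)
      stop("parallel_transport: x is not tangent at the vertex")
  }
  ip0 <- lorentz_inner(mu0, mu)          # = -mu[k] <= -1
  denom <- 1 - ip0
  stopifnot(denom >= 2 - 1e-9)
  x + (lorentz_inner(mu + ip0 * mu0, x) / denom) * (mu0 + mu)
}

#' Orthogonal projection of an ambient vector onto a tangent space
#'
#' \code{g + lorentz_inner(u, g) * u} — the Lorentz-orthogonal projection
#' of the ambient gradient \code{g} onto the tangent space at \code{u};
#' the Riemannian gradient step applies this before the exponential map.
#'
#' @param u point on the hyperboloid.
#' @param g ambient numeric vector of the same length.
#' @return tangent vector at \code{u}.
#' @export
project_to_tangent <- function(u, g) {
  g + lorentz_inner(u, g) * u
}

#' Lift coordinates onto the hyperboloid
#'
#' Completes a d-vector of space-like coordinates with the time-like
#' coordinate \code{sqrt(1 + sum(z^2))}, which satisfies the constraint
#' exactly.
#'
#' @param z numeric vector of length d (or m x d matrix of rows to lift).
#' @return a (d+1)-vector on the hyperboloid (or m x (d+1) matrix).
#' @export
lift_to_hyperboloid <- function(z) {
  if (is.matrix(z)) return(cbind(z, sqrt(1 + rowSums(z^2))))
  c(z, sqrt(1 + sum(z^2)))
}

#' Re-project a drifted point onto the hyperboloid
#'
#' Recomputes the last coordinate from the first d
#' (\code{sqrt(1 + sum(x[1:d]^2))}).  Cheap, exact, and preserves the
#' space-like coordinates; applied after every optimizer update to keep
#' floating-point drift from accumulating.
#'
#' @param x numeric vector, or matrix of row points.
#' @return point(s) satisfying the constraint to machine precision.
#' @export
reproject_hyperboloid <- function(x) {
  if (is.matrix(x)) {
    n <- ncol(x)
    x[, n] <- sqrt(1 + rowSums(x[, -n, drop = FALSE]^2))
    return(x)
  }
  n <- length(x)
  x[n] <- sqrt(1 + sum(x[-n]^2))
  x
}

## Vertex of H^d embedded in R^{d,1}
hyperboloid_vertex <- function(d) c(rep(0, d), 1)
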