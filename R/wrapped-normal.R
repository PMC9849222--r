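#' Sample from the wrapped (pseudo-hyperbolic Gaussian) normal
#'
#' Draws points from the wrapped normal G(mu, sigma2 * I) on the
#' hyperboloid by the standard three-step construction: (a) sample an
#' isotropic Gaussian vector in the tangent space at the vertex
#' (embedded with last coordinate 0), (b) parallel-transport it to the
#' tangent space at \code{mu}, (c) push it onto the manifold with the
#' exponential map.
#'
#' @param n number of draws.
#' @param mu location, a point on the hyperboloid of ambient dimension
#'   d+1 (the vertex \code{c(rep(0, d), 1)} for a prior at the origin).
#' @param sigma2 isotropic tangent-space variance, > 0.
#' @param seed optional integer; when given, the draw is deterministic.
#' @return an n x (d+1) matrix whose rows lie on the hyperboloid.
#' @examples
#' z <- rwrapped_normal(5, mu = c(0, 0, 1), sigma2 = 0.1, seed = 1)
#' @export
rwrapped_normal <- function(n, mu, sigma2, seed = NULL) {
  if (sigma2 <= 0) stop("rwrapped_normal: sigma2 must be > 0")
  if (n < 1L) stop("rwrapped_normal: n must be >= 1")
  assert_on_hyperboloid(mu, what = "mu")
  if (!is.null(seed)) set.seed(as.integer(seed))
  d <- length(mu) - 1L
  X <- matrix(stats::rnorm(n * d, sd = sqrt(sigma2)), nrow = n, ncol = d)
  X <- cbind(X, 0)                       # T_{mu0} is the hyperplane x_{d+1} = 0
  at_vertex <- all(mu[seq_len(d)] == 0)
  if (at_vertex) {                       # transport is the identity: vectorize
    t <- sqrt(rowSums(X[, seq_len(d), drop = FALSE]^2))
    sinhc <- ifelse(t < 1e-6, 1 + t^2 / 6 + t^4 / 120, sinh(t) / t)
    out <- sinhc * X
    out[, d + 1L] <- cosh(t)
    return(reproject_hyperboloid(out))
  }
  out <- matrix(0, n, d + 1L)
  for (i in seq_len(n)) {
    y <- parallel_transport(mu, X[i, ], check = FALSE)
    out[i, ] <- exp_map(mu, y, check = FALSE)
  }
  out
}

#' Wrapped-normal log density on the hyperboloid
#'
#' Log density of G(mu, sigma2 * I) at a point \code{z}, using the
#' closed-form change-of-variables correction:
#' \code{log N(xbar | 0, sigma2 I) - (d - 1) * log(sinh(r) / r)} where
#' \code{r = hyperbolic_distance(mu, z)} and \code{xbar} is the tangent
#' pre-image of \code{z} (whose Lorentzian norm is \code{r}).  The
#' correction term has limit 0 as \code{r -> 0}, handled by series.
#'
#' @param z point on the hyperboloid (or matrix of row points).
#' @param mu location on the hyperboloid.
#' @param sigma2 isotropic variance, > 0.
#' @param log if \code{FALSE}, return the density itself.
#' @return log density value(s).
#' @export
dwrapped_normal <- function(z, mu, sigma2, log = TRUE) {
  if (sigma2 <= 0) stop("dwrapped_normal: sigma2 must be > 0")
  if (is.matrix(z)) {
    val <- apply(z, 1L, dwrapped_normal, mu = mu, sigma2 = sigma2, log = TRUE)
    return(if (log) val else exp(val))
  }
  assert_on_hyperboloid(z, what = "z")
  assert_on_hyperboloid(mu, what = "mu")
  d <- length(mu) - 1L
  r <- hyperbolic_distance(mu, z, check = FALSE)
  # full Gaussian normalizer so the density integrates to 1 over H^d
  lognorm <- -0.5 * d * base::log(2 * pi * sigma2)
  logN <- lognorm - r^2 / (2 * sigma2)
  val <- logN - (d - 1) * log_sinh_ratio(r)
  if (log) val else exp(val)
}

## log(sinh(r) / r), with series limit r -> 0:
## sinh(r)/r = 1 + r^2/6 + r^4/120 => log(...) ~ r^2/6 - r^4/180
log_sinh_ratio <- function(r) {
  ifelse(r < 1e-4, r^2 / 6 - r^4 / 180, base::log(sinh(r) / r))
}
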