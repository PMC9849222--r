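# Random hyperboloid points, tangent vectors and small problem instances
# used across the suite.  Everything is generated in code under explicit
# seeds; no fixture files.

random_point <- function(d = 2, scale = 1) {
  lift_to_hyperboloid(stats::rnorm(d, sd = scale))
}

random_points <- function(n, d = 2, scale = 1) {
  lift_to_hyperboloid(matrix(stats::rnorm(n * d, sd = scale), n, d))
}

# tangent vector at p obtained by projecting an ambient Gaussian vector
random_tangent <- function(p, scale = 1) {
  project_to_tangent(p, stats::rnorm(length(p), sd = scale))
}

# small random model instance for gradient and loss checks
random_instance <- function(m = 6, n = 5, d = 3, scale = 0.7) {
  list(U = random_points(m, d, scale),
       V = random_points(n, d, scale),
       R = matrix(stats::rbinom(m * n, 1, 0.4), m, n),
       S = sym_unif(m), T = sym_unif(n))
}

sym_unif <- function(m) {
  S <- matrix(stats::runif(m * m), m, m)
  (S + t(S)) / 2
}

vertex <- function(d) c(rep(0, d), 1)
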