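test_that("lorentz_inner matches its closed form and rejects bad shapes", {
  expect_equal(lorentz_inner(c(0, 0, 1), c(0, 0, 1)), -1)
  expect_equal(lorentz_inner(c(1, 0, 0), c(0, 1, 0)), 0)
  expect_equal(lorentz_inner(c(sinh(1), 0, cosh(1)), c(0, 0, 1)), -cosh(1))
  # symmetry on random vectors
  set.seed(1)
  x <- rnorm(4); y <- rnorm(4)
  expect_equal(lorentz_inner(x, y), lorentz_inner(y, x))
  expect_error(lorentz_inner(1:3, 1:4), "equal length")
  expect_error(lorentz_inner(1, 2), "length")
})

test_that("hyperbolic distance: identity, closed form, off-manifold rejection", {
  mu0 <- vertex(2)
  expect_equal(hyperbolic_distance(mu0, mu0), 0)
  expect_equal(hyperbolic_distance(mu0, c(sinh(2), 0, cosh(2))), 2)
  expect_error(hyperbolic_distance(c(1, 1, 1), mu0), "hyperboloid")
})

test_that("geodesic distance matches a discretized path-length oracle", {
  # chord lengths measured with the ambient Lorentzian quadratic form
  # (local metric), not with acosh: an independent route to arc length
  set.seed(7)
  for (rep in 1:3) {
    x <- random_point(2); y <- random_point(2)
    v <- log_map(x, y)
    nseg <- 1e4
    pts <- t(vapply(seq(0, 1, length.out = nseg + 1),
                    function(s) exp_map(x, s * v, check = FALSE),
                    numeric(3)))
    diffs <- pts[-1, ] - pts[-(nseg + 1), ]
    seg <- sqrt(pmax(rowSums(diffs[, 1:2, drop = FALSE]^2) - diffs[, 3]^2, 0))
    expect_equal(sum(seg), hyperbolic_distance(x, y), tolerance = 1e-4)
  }
})

test_that("squared Lorentzian distance and its link to geodesic distance", {
  mu0 <- vertex(2)
  expect_equal(sq_lorentz_distance(mu0, mu0), 0)
  expect_equal(sq_lorentz_distance(mu0, c(sinh(1), 0, cosh(1))),
               2 * cosh(1) - 2)
  set.seed(2)
  for (i in 1:100) {
    x <- random_point(3); y <- random_point(3)
    dl2 <- sq_lorentz_distance(x, y)
    dh <- hyperbolic_distance(x, y)
    expect_lt(abs(dl2 - 2 * (cosh(dh) - 1)), 1e-9)
    expect_gte(dl2, 0)
  }
})

test_that("exp_map: zero vector, closed form at the vertex, constraint and length", {
  mu0 <- vertex(3)
  expect_equal(exp_map(mu0, rep(0, 4)), mu0)
  t <- 1.3
  expect_equal(exp_map(vertex(2), c(t, 0, 0)),
               c(sinh(t), 0, cosh(t)), tolerance = 1e-12)
  set.seed(3)
  for (i in 1:100) {
    mu <- random_point(3)
    y <- random_tangent(mu)
    out <- exp_map(mu, y)
    expect_lt(abs(lorentz_inner(out, out) + 1), 1e-9)
    expect_gte(out[4], 1)
    nrm <- sqrt(max(lorentz_inner(y, y), 0))
    expect_lt(abs(hyperbolic_distance(mu, out) - nrm), 1e-8)
  }
  expect_error(exp_map(mu0, c(0, 0, 0, 1)), "tangent")
})

test_that("log_map inverts exp_map and matches the vertex closed form", {
  mu0 <- vertex(2)
  expect_equal(log_map(mu0, mu0), c(0, 0, 0))
  expect_equal(log_map(mu0, c(sinh(2), 0, cosh(2))), c(2, 0, 0),
               tolerance = 1e-12)
  set.seed(4)
  for (i in 1:100) {
    mu <- random_point(3); x <- random_point(3)
    v <- log_map(mu, x)
    expect_lt(abs(lorentz_inner(mu, v)), 1e-9)
    expect_lt(max(abs(exp_map(mu, v) - x)), 1e-8)
    expect_lt(abs(sqrt(lorentz_inner(v, v)) - hyperbolic_distance(mu, x)),
              1e-9)
  }
})

test_that("parallel transport is the identity at the vertex and an isometry", {
  mu0 <- vertex(2)
  x <- c(0.3, -1.2, 0)
  expect_equal(parallel_transport(mu0, x), x)
  set.seed(5)
  for (i in 1:100) {
    mu <- random_point(2)
    x1 <- c(rnorm(2), 0); x2 <- c(rnorm(2), 0)
    g1 <- parallel_transport(mu, x1)
    g2 <- parallel_transport(mu, x2)
    expect_lt(abs(lorentz_inner(g1, g2) - lorentz_inner(x1, x2)), 1e-9)
    expect_lt(abs(lorentz_inner(mu, g1)), 1e-9)
  }
  expect_error(parallel_transport(random_point(2), c(1, 1, 1)), "tangent")
})

test_that("tangent projection: fixed points, kernel, tangency", {
  set.seed(6)
  u <- random_point(3)
  tg <- random_tangent(u)
  expect_equal(project_to_tangent(u, tg), tg, tolerance = 1e-12)
  expect_equal(project_to_tangent(u, u), rep(0, 4), tolerance = 1e-12)
  for (i in 1:100) {
    u <- random_point(3); g <- rnorm(4)
    expect_lt(abs(lorentz_inner(u, project_to_tangent(u, g))), 1e-9)
  }
})

test_that("lift_to_hyperboloid satisfies the constraint exactly", {
  expect_equal(lift_to_hyperboloid(c(0, 0)), vertex(2))
  expect_equal(lift_to_hyperboloid(c(sinh(1), 0)), c(sinh(1), 0, cosh(1)))
  set.seed(8)
  Z <- matrix(rnorm(300), 100, 3)
  X <- lift_to_hyperboloid(Z)
  q <- rowSums(X[, 1:3]^2) - X[, 4]^2
  expect_lt(max(abs(q + 1)), 1e-9)
})

test_that("triangle inequality holds on random triples", {
  set.seed(9)
  for (i in 1:1000) {
    p <- random_points(3, 3)
    dab <- hyperbolic_distance(p[1, ], p[2, ], check = FALSE)
    dbc <- hyperbolic_distance(p[2, ], p[3, ], check = FALSE)
    dac <- hyperbolic_distance(p[1, ], p[3, ], check = FALSE)
    expect_lte(dac, dab + dbc + 1e-9)
  }
})

test_that("the Lorentzian form is positive definite on tangent spaces", {
  set.seed(10)
  for (i in 1:1000) {
    p <- random_point(3)
    v <- random_tangent(p)
    expect_gt(lorentz_inner(v, v), 0)
  }
})
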