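test_that("simplex membership test accepts the simplex and rejects the rest", {
  expect_true(assert_on_simplex(c(0.5, 0.5)))
  expect_true(assert_on_simplex(c(1, 0, 0)))  # vertices included
  expect_false(assert_on_simplex(c(1.1, -0.1)))
  expect_false(assert_on_simplex(c(0.5, 0.4)))
  expect_false(assert_on_simplex(c(NaN, 1)))
  # closure under convex combination
  set.seed(4)
  for (rep in 1:50) {
    d <- sample(2:6, 1)
    x0 <- random_simplex_rows(1, d); x1 <- random_simplex_rows(1, d)
    a <- runif(1)
    expect_true(assert_on_simplex((1 - a) * x0 + a * x1))
  }
})

test_that("Euclidean simplex projection is exact, idempotent, non-expansive", {
  # already on the simplex: unchanged
  expect_equal(project_to_simplex(c(0.2, 0.3, 0.5)),
               matrix(c(0.2, 0.3, 0.5), 1))
  # scaled vertex projects to the vertex
  expect_equal(project_to_simplex(c(2, 0, 0)), matrix(c(1, 0, 0), 1))
  set.seed(9)
  rows <- matrix(runif(300 * 3, -1, 1), 300, 3)
  p <- project_to_simplex(rows)
  expect_rows_on_simplex(p, tol = 1e-9)
  # idempotence
  expect_equal(project_to_simplex(p), p, tolerance = 1e-12)
  expect_error(project_to_simplex(matrix(c(1, NA), 1)), "non-finite")
})

test_that("projection matches a brute-force grid minimizer", {
  # oracle: dense barycentric grid over S_3, pick the grid point nearest to y
  grid_project <- function(y, steps = 120) {
    best <- NULL; bestd <- Inf
    for (i in 0:steps) for (j in 0:(steps - i)) {
      x <- c(i, j, steps - i - j) / steps
      d2 <- sum((x - y)^2)
      if (d2 < bestd) { bestd <- d2; best <- x }
    }
    best
  }
  set.seed(12)
  ys <- matrix(runif(15, -1, 1), 5, 3)
  p <- project_to_simplex(ys)
  for (k in 1:5) {
    o <- grid_project(ys[k, ])
    # grid resolution 1/120 bounds the gap between minimizers
    expect_lt(max(abs(p[k, ] - o)), 2 / 120)
    # and the analytic projection is at least as close to y
    expect_lte(sum((p[k, ] - ys[k, ])^2), sum((o - ys[k, ])^2) + 1e-12)
  }
})

test_that("non-expansiveness of projection holds on random pairs", {
  set.seed(10)
  x <- matrix(runif(600, -2, 2), 200, 3)
  y <- x + matrix(rnorm(600, sd = 0.5), 200, 3)
  dp <- rowSums((project_to_simplex(x) - project_to_simplex(y))^2)
  d0 <- rowSums((x - y)^2)
  expect_true(all(dp <= d0 + 1e-12))
})

test_that("categorical prior families have the stated support and moments", {
  set.seed(100)
  m <- 20000
  # barycenter with no blur: every row is the center point
  b <- sample_categorical_prior(categorical_prior_spec("barycenter",
                                                       blur_sigma = 0), m = 5,
                                d = 4)
  expect_equal(b, matrix(0.25, 5, 4))
  # uniform-simplex: flat Dirichlet, per-coordinate mean 1/3,
  # var = 2/(9*4) / ... use 3 SE of the known Dirichlet(1,1,1) moments
  u <- sample_categorical_prior(categorical_prior_spec("uniform-simplex"),
                                m = m, d = 3)
  expect_rows_on_simplex(u)
  se <- sqrt(1 / 18) / sqrt(m)  # var of Dir(1,1,1) coordinate = 1/18
  expect_true(all(abs(colMeans(u) - 1 / 3) < 3 * se + 1e-12))
  # marginal-simplex without blur: one-hot vertices at frequencies q
  q <- c(0.7, 0.2, 0.1)
  mg <- sample_categorical_prior(
    categorical_prior_spec("marginal-simplex", blur_sigma = 0, q = q), m, 3)
  expect_true(all(mg %in% c(0, 1)))
  freq <- colMeans(mg)
  expect_true(all(abs(freq - q) < 3 * sqrt(q * (1 - q) / m)))
  # blurred version stays on the simplex but leaves the vertex set
  mgb <- sample_categorical_prior(
    categorical_prior_spec("marginal-simplex", blur_sigma = 0.15, q = q),
    1000, 3)
  expect_rows_on_simplex(mgb, tol = 1e-9)
  expect_gt(mean(apply(mgb, 1, max) < 1), 0.5)
  # gaussian: unconstrained
  gs <- sample_categorical_prior(categorical_prior_spec("gaussian"), m, 3)
  expect_false(assert_on_simplex(gs))
  expect_lt(abs(mean(gs)), 3 / sqrt(3 * m))
  # validation errors
  expect_error(categorical_prior_spec("marginal-simplex", q = NULL),
               "requires marginals")
  expect_error(categorical_prior_spec("barycenter", blur_sigma = -1), ">= 0")
  expect_error(categorical_prior_spec("marginal-simplex", q = c(2, -1)),
               "simplex")
})

test_that("Dirichlet path has concentration 1 + e_i * omega_t and exact moments", {
  s <- interpolant_schedule(1)
  # alpha = 0 -> omega = 1 -> gamma = (1,...,2,...,1)
  expect_equal(dirichlet_path_gamma(2, 4, 0, s, omega_max = 10),
               c(1, 2, 1, 1))
  # moment oracle: mean = gamma / sum(gamma)
  set.seed(50)
  m <- 20000
  t <- 0.6
  om <- 100
  x <- dirichlet_path_sample(1, 3, t, s, m = m, omega_max = om)
  expect_rows_on_simplex(x)
  gam <- dirichlet_path_gamma(1, 3, t, s, omega_max = om)
  mu <- gam / sum(gam)
  sg <- sum(gam)
  se <- sqrt(mu * (1 - mu) / (sg + 1)) / sqrt(m)
  expect_true(all(abs(colMeans(x) - mu) < 3 * se))
  # large omega concentrates mass on the target vertex
  xl <- dirichlet_path_sample(2, 3, 1, s, m = 2000, omega_max = 1e4)
  expect_gt(mean(xl[, 2]), 0.99)
  expect_error(dirichlet_path_sample(5, 3, 0.5, s), "out of range")
  expect_error(dirichlet_path_sample(1, 3, 0.5, s, omega_max = -1), "> 0")
})
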