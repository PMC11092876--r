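make_pair <- function(n = 4, seed = 7) {
  set.seed(seed)
  g1 <- random_relaxed_graph(n)
  g0 <- random_relaxed_graph(n)
  conditional_pair(g0, g1)
}

test_that("interpolation returns exact endpoints and convex midpoints", {
  pair <- make_pair()
  ss <- schedule_set()
  expect_equal(interpolate_pair(pair, ss, 0), pair$g0, ignore_attr = TRUE)
  expect_equal(interpolate_pair(pair, ss, 1), pair$g1, ignore_attr = TRUE)
  # nu = 1, alpha(0.5) = 0.5: exact midpoint of every modality
  mid <- interpolate_pair(pair, ss, 0.5)
  expect_equal(mid$A, (pair$g0$A + pair$g1$A) / 2)
  expect_equal(mid$X, (pair$g0$X + pair$g1$X) / 2)
  # positions example: alpha^X = 0.25 moves a quarter of the way
  t25 <- 2 / pi * asin(sqrt(0.25))
  g0 <- pair$g0; g0$X[1, ] <- c(0, 0, 0)
  g1 <- pair$g1; g1$X[1, ] <- c(2, 0, 0)
  p <- conditional_pair(g0, g1)
  expect_equal(interpolate_pair(p, ss, t25)$X[1, ], c(0.5, 0, 0),
               tolerance = 1e-10)
  expect_error(conditional_pair(pair$g0, random_relaxed_graph(5)),
               "atom count")
})

test_that("conditional vector field matches alpha'(g1 - g0) and its endpoint form", {
  ss <- schedule_set(nu_x = 2, nu_a = 1, nu_c = 0.5, nu_e = 3)
  set.seed(21)
  for (rep in 1:10) {
    pair <- make_pair(n = 3, seed = rep)
    t <- runif(1, 0, 0.99)
    u <- conditional_vf(pair, ss, t)
    expect_equal(u$A,
                 schedule_alpha_prime(ss$A, t) * (pair$g1$A - pair$g0$A))
    # identity: alpha'(g1 - g0) == (alpha'/(1-alpha))(g1 - g_t)
    g_t <- interpolate_pair(pair, ss, t)
    u2 <- endpoint_vf(g_t, pair$g1, ss, t)
    for (m in c("X", "A", "C", "E")) {
      expect_equal(u[[m]], u2[[m]], tolerance = 1e-8)
    }
  }
  # g0 == g1 gives the zero field for all t
  g <- random_relaxed_graph(3)
  same <- conditional_pair(g, g)
  u <- conditional_vf(same, ss, 0.7)
  expect_equal(u$X, matrix(0, 3, 3), ignore_attr = TRUE)
})

test_that("endpoint field scales the gap by alpha'/(1-alpha) and is linear", {
  ss <- schedule_set()
  set.seed(5)
  g_t <- random_relaxed_graph(3)
  g1h <- random_relaxed_graph(3)
  t <- 0.5  # alpha = 0.5, alpha' = pi/2, weight = pi
  u <- endpoint_vf(g_t, g1h, ss, t)
  expect_equal(u$X, pi * (g1h$X - g_t$X), tolerance = 1e-12)
  # g1_hat == g_t gives zero field
  u0 <- endpoint_vf(g_t, g_t, ss, t)
  expect_equal(max(abs(u0$A)), 0)
  # doubling the gap doubles the field
  g2 <- g_t
  g2$X <- g_t$X + 2 * (g1h$X - g_t$X)
  expect_equal(endpoint_vf(g_t, g2, ss, t)$X, 2 * u$X, tolerance = 1e-12)
  expect_error(endpoint_vf(g_t, g1h, ss, 1), "alpha_t = 1")
})

test_that("training loss reproduces hand-computed values", {
  cb <- default_cb
  # single atom, no bonds: X error (1,0,0), perfect categorical prediction
  mk <- function(x) {
    molecule_graph(matrix(x, 1, 3), to_onehot(2, cb$n_a),
                   to_onehot(2, cb$n_c),
                   matrix(numeric(0), 0, cb$n_e), cb)
  }
  g1 <- mk(c(0, 0, 0))
  g0 <- mk(c(5, 5, 5))
  pair <- conditional_pair(g0, g1)
  pred <- mk(c(1, 0, 0))
  ss <- schedule_set()
  t <- 0.5  # w(t) = 1 for every modality
  l <- training_loss(pair, pred, ss, t, "endpoint", eta = c(3, 0, 0, 0))
  expect_equal(l$total, 3 * 1 * 1)  # eta_X * w * ||(1,0,0)||^2
  # eta = (1,0,0,0) isolates the position term
  l1 <- training_loss(pair, pred, ss, t, "endpoint", eta = c(1, 0, 0, 0))
  expect_equal(l1$total, l1$X)
  # perfect endpoint prediction: position term 0, cross entropy ~ 0
  lp <- training_loss(pair, g1, ss, t, "endpoint")
  expect_equal(lp$X, 0)
  expect_lt(lp$A, 1e-10)
  # vector-field objective: zero loss iff prediction equals conditional vf
  u <- conditional_vf(pair, ss, t)
  lv <- training_loss(pair, u, ss, t, "vector_field")
  expect_equal(lv$total, 0)
  u$X <- u$X + 1
  expect_gt(training_loss(pair, u, ss, t, "vector_field")$total, 0)
})

test_that("training loss is invariant to consistent atom relabeling", {
  ss <- schedule_set(2, 1, 1, 0.5)
  set.seed(33)
  for (rep in 1:5) {
    n <- 5
    g1 <- random_relaxed_graph(n)
    g1$A <- to_onehot(max.col(g1$A), default_cb$n_a)
    g1$C <- to_onehot(max.col(g1$C), default_cb$n_c)
    g1$E <- to_onehot(max.col(g1$E), default_cb$n_e)
    g0 <- random_relaxed_graph(n)
    pred <- random_relaxed_graph(n)
    t <- runif(1)
    base <- training_loss(conditional_pair(g0, g1), pred, ss, t, "endpoint")
    perm <- sample(n)
    permuted <- training_loss(
      conditional_pair(permute_molecule(g0, perm), permute_molecule(g1, perm)),
      permute_molecule(pred, perm), ss, t, "endpoint")
    expect_equal(base$total, permuted$total, tolerance = 1e-6)
  }
})

test_that("raw endpoint weight is available and diverges from w(t) near t=1", {
  ss <- schedule_set()
  pair <- make_pair(3)
  pred <- random_relaxed_graph(3)
  t <- 0.95
  clamped <- training_loss(pair, pred, ss, t, "endpoint")
  raw <- training_loss(pair, pred, ss, t, "endpoint", raw_weight = TRUE)
  expect_gt(raw$X, clamped$X)  # raw alpha'/(1-alpha) exceeds the 1.5 clamp
})
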