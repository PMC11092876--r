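relaxed_state <- function(n = 5, seed = 40) {
  set.seed(seed)
  g <- random_relaxed_graph(n)
  g$X <- g$X - matrix(colMeans(g$X), n, 3, byrow = TRUE)
  g
}

test_that("gvp layer honors its equivariance contract", {
  gvp <- molfm:::gvp_forward
  init <- molfm:::init_gvp
  set.seed(41)
  n <- 6
  s <- matrix(rnorm(n * 5), n, 5)
  v <- molfm:::vec3(matrix(rnorm(n * 3), n, 3), matrix(rnorm(n * 3), n, 3),
                    matrix(rnorm(n * 3), n, 3))
  rotate_v <- function(v, r) {
    comp <- function(k) v$x * r[1, k] + v$y * r[2, k] + v$z * r[3, k]
    molfm:::vec3(comp(1), comp(2), comp(3))
  }
  for (cross in c(TRUE, FALSE)) {
    p <- init(5, 3, 4, 2, 3, cross)
    out <- gvp(p, s, v, cross)
    for (rep in 1:5) {
      r <- random_rotation()
      out_r <- gvp(p, s, rotate_v(v, r), cross)
      # scalars invariant, vectors equivariant
      expect_equal(out_r$s, out$s, tolerance = 1e-10)
      rot_out <- rotate_v(out$v, r)
      expect_equal(out_r$v$x, rot_out$x, tolerance = 1e-10)
    }
    # zero vector inputs: cross contributions vanish, outputs are zero vectors
    vz <- molfm:::vec3(matrix(0, n, 3), matrix(0, n, 3), matrix(0, n, 3))
    outz <- gvp(p, s, vz, cross)
    expect_equal(max(abs(outz$v$x)), 0)
    # mirror: cross products break reflection equivariance, plain GVP keeps it
    m <- diag(c(-1, 1, 1))
    out_m <- gvp(p, s, rotate_v(v, m), cross)
    mirrored <- rotate_v(out$v, m)
    gap <- max(abs(out_m$v$x - mirrored$x), abs(out_m$v$y - mirrored$y),
               abs(out_m$v$z - mirrored$z))
    if (cross) expect_gt(gap, 1e-3) else expect_lt(gap, 1e-12)
  }
  expect_error(gvp(molfm:::init_gvp(4, 3, 4, 2, 3, TRUE), s, v, TRUE))
})

test_that("molecule update stack is permutation and SE(3) equivariant", {
  g <- relaxed_state(5)
  set.seed(42)
  m <- tiny_model()
  t <- 0.3
  p1 <- predict_endpoint(m, g, t)
  # permutation: predict on permuted input == permuted prediction
  perm <- sample(g$N)
  p_perm <- predict_endpoint(m, permute_molecule(g, perm), t)
  expect_equal(p_perm$X, p1$X[perm, ], tolerance = 1e-6)
  expect_equal(p_perm$A, p1$A[perm, ], tolerance = 1e-6)
  src <- pair_index(g$N)
  expect_equal(p_perm$E,
               permute_molecule(p1, perm)$E, tolerance = 1e-6)
  # translation: positions co-translate, everything else unchanged
  tr <- c(1.5, -2, 0.25)
  g_tr <- g; g_tr$X <- sweep(g$X, 2, -tr)
  p_tr <- predict_endpoint(m, g_tr, t)
  expect_equal(p_tr$X, sweep(p1$X, 2, -tr), tolerance = 1e-5)
  expect_equal(p_tr$A, p1$A, tolerance = 1e-5)
  # rotation: positions co-rotate, categorical outputs unchanged
  r <- random_rotation()
  g_r <- g; g_r$X <- g$X %*% r
  p_r <- predict_endpoint(m, g_r, t)
  expect_equal(p_r$X, p1$X %*% r, tolerance = 1e-5)
  expect_equal(p_r$E, p1$E, tolerance = 1e-5)
})

test_that("endpoint heads are simplex-valued and bond rows pair-symmetric", {
  g <- relaxed_state(6)
  m <- tiny_model()
  p <- predict_endpoint(m, g, 0.6)
  expect_rows_on_simplex(p$A)
  expect_rows_on_simplex(p$C)
  expect_rows_on_simplex(p$E)
  expect_equal(nrow(p$E), (6^2 - 6) / 2)  # one row per unordered pair
  # swapping the two atoms of a pair leaves its bond prediction unchanged:
  # permute atoms 1 and 2 and compare the {1,2} row
  perm <- c(2L, 1L, 3:6)
  p_sw <- predict_endpoint(m, permute_molecule(g, perm), 0.6)
  k12 <- pair_row(1, 2, 6)
  expect_equal(p_sw$E[k12, ], p$E[k12, ], tolerance = 1e-7)
  expect_error(predict_endpoint(m, g, 1.5), "\\[0, 1\\]")
  expect_error(predict_vf(m, g, 0.5), "endpoint objective")
})

test_that("vector-field heads are unconstrained and equivariant", {
  g <- relaxed_state(4)
  m <- tiny_model(objective = "vector_field")
  u <- predict_vf(m, g, 0.4)
  # no softmax: categorical tangents are not on the simplex
  expect_false(assert_on_simplex(u$A))
  r <- random_rotation()
  g_r <- g; g_r$X <- g$X %*% r
  u_r <- predict_vf(m, g_r, 0.4)
  expect_equal(u_r$X, u$X %*% r, tolerance = 1e-5)
  expect_equal(u_r$A, u$A, tolerance = 1e-5)
  perm <- sample(4)
  u_p <- predict_vf(m, permute_molecule(g, perm), 0.4)
  expect_equal(u_p$X, u$X[perm, ], tolerance = 1e-6)
  expect_error(predict_endpoint(m, g, 0.4), "vector_field")
})

test_that("reflection sensitivity switches with the cross-product flag", {
  g <- relaxed_state(5, seed = 43)
  mirror <- diag(c(-1, 1, 1))
  g_m <- g; g_m$X <- g$X %*% mirror
  set.seed(44)
  m_on <- tiny_model(n_blocks = 2, cross_products = TRUE)
  m_off <- tiny_model(n_blocks = 2, cross_products = FALSE)
  p_on <- predict_endpoint(m_on, g, 0.3)
  p_on_m <- predict_endpoint(m_on, g_m, 0.3)
  expect_gt(max(abs(p_on$X %*% mirror - p_on_m$X)), 1e-3)
  p_off <- predict_endpoint(m_off, g, 0.3)
  p_off_m <- predict_endpoint(m_off, g_m, 0.3)
  expect_lt(max(abs(p_off$X %*% mirror - p_off_m$X)), 1e-10)
})

test_that("single-atom molecules pass through the network", {
  cb <- default_cb
  g <- molecule_graph(matrix(0, 1, 3), to_onehot(2, cb$n_a),
                      to_onehot(2, cb$n_c), matrix(numeric(0), 0, cb$n_e), cb)
  m <- tiny_model()
  p <- predict_endpoint(m, g, 0.5)
  expect_equal(p$N, 1L)
  expect_rows_on_simplex(p$A)
  expect_equal(nrow(p$E), 0L)
})

test_that("checkpoint round trip preserves predictions", {
  g <- relaxed_state(4)
  m <- tiny_model()
  prior <- molecule_prior_spec(categorical_prior_spec("uniform-simplex"),
                               categorical_prior_spec("uniform-simplex"),
                               categorical_prior_spec("uniform-simplex"),
                               c(`4` = 1))
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(m, path, prior = prior)
  ck <- load_checkpoint(path)
  p1 <- predict_endpoint(m, g, 0.3)
  p2 <- predict_endpoint(ck$model, g, 0.3)
  expect_equal(p2$X, p1$X, tolerance = 1e-12)
  expect_equal(p2$E, p1$E, tolerance = 1e-12)
  expect_equal(ck$prior$atom_count_hist, prior$atom_count_hist)
})
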