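# gradient checks of the tape engine against central finite differences

numeric_grad <- function(f, x, eps = 1e-6) {
  g <- x
  for (i in seq_along(x)) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}

test_that("composite scalar graphs differentiate correctly", {
  ad <- asNamespace("molfm")
  set.seed(1)
  a0 <- matrix(rnorm(12), 3, 4)
  b0 <- matrix(rnorm(8), 4, 2)
  bias0 <- matrix(rnorm(2), 1, 2)
  f <- function(a, b, bias) {
    h <- ad$ad_tanh(ad$ad_addbias(ad$ad_matmul(a, b), bias))
    p <- ad$ad_softmax_rows(h)
    lp <- ad$ad_log(ad$ad_adds(p, 1e-12))
    as.numeric(ad$ad_value(ad$ad_sum(ad$ad_mul(lp, p))))  # -entropy
  }
  tape <- ad$ad_tape()
  an <- ad$ad_leaf(tape, a0); bn <- ad$ad_leaf(tape, b0)
  biasn <- ad$ad_leaf(tape, bias0)
  h <- ad$ad_tanh(ad$ad_addbias(ad$ad_matmul(an, bn), biasn))
  p <- ad$ad_softmax_rows(h)
  loss <- ad$ad_sum(ad$ad_mul(ad$ad_log(ad$ad_adds(p, 1e-12)), p))
  grads <- ad$ad_backward(loss)
  ga <- grads[[an$id]]; gb <- grads[[bn$id]]; gbias <- grads[[biasn$id]]
  expect_equal(ga, matrix(numeric_grad(function(x) f(matrix(x, 3, 4), b0, bias0),
                                       as.numeric(a0)), 3, 4),
               tolerance = 1e-5)
  expect_equal(gb, matrix(numeric_grad(function(x) f(a0, matrix(x, 4, 2), bias0),
                                       as.numeric(b0)), 4, 2),
               tolerance = 1e-5)
  expect_equal(gbias, matrix(numeric_grad(function(x) f(a0, b0, matrix(x, 1, 2)),
                                          as.numeric(bias0)), 1, 2),
               tolerance = 1e-5)
})

test_that("gather / rowsum_by / rbf / cbind differentiate correctly", {
  ad <- asNamespace("molfm")
  set.seed(2)
  x0 <- matrix(rnorm(10), 5, 2)
  idx <- c(2L, 2L, 5L, 1L)
  groups <- c(1L, 3L, 3L, 2L)
  centers <- c(0, 1, 2)
  f <- function(x) {
    g <- ad$ad_gather(x, idx)
    s <- ad$ad_rowsum_by(g, groups, 3L)
    d <- ad$ad_sqrt(ad$ad_adds(ad$ad_sum(ad$ad_mul(s, s)), 1e-9))
    as.numeric(ad$ad_value(d))
  }
  tape <- ad$ad_tape()
  xn <- ad$ad_leaf(tape, x0)
  g <- ad$ad_gather(xn, idx)
  s <- ad$ad_rowsum_by(g, groups, 3L)
  loss <- ad$ad_sqrt(ad$ad_adds(ad$ad_sum(ad$ad_mul(s, s)), 1e-9))
  grads <- ad$ad_backward(loss)
  expect_equal(grads[[xn$id]],
               matrix(numeric_grad(function(v) f(matrix(v, 5, 2)),
                                   as.numeric(x0)), 5, 2),
               tolerance = 1e-5)
  # rbf of a distance column
  d0 <- matrix(abs(rnorm(4)) + 0.1, 4, 1)
  frbf <- function(v) {
    y <- ad$ad_rbf(matrix(v, 4, 1), centers, 0.7)
    sum(ad$ad_value(y) * seq_len(12))
  }
  tape <- ad$ad_tape()
  dn <- ad$ad_leaf(tape, d0)
  y <- ad$ad_rbf(dn, centers, 0.7)
  loss <- ad$ad_sum(ad$ad_mul(y, matrix(seq_len(12), 4, 3)))
  grads <- ad$ad_backward(loss)
  expect_equal(grads[[dn$id]],
               matrix(numeric_grad(frbf, as.numeric(d0)), 4, 1),
               tolerance = 1e-5)
  # cbind splits gradients by column blocks
  a0 <- matrix(rnorm(6), 3, 2); b0 <- matrix(rnorm(3), 3, 1)
  tape <- ad$ad_tape()
  an <- ad$ad_leaf(tape, a0); bn <- ad$ad_leaf(tape, b0)
  cc <- ad$ad_cbind(an, matrix(1, 3, 2), bn)
  w <- matrix(rnorm(15), 3, 5)
  loss <- ad$ad_sum(ad$ad_mul(cc, w))
  grads <- ad$ad_backward(loss)
  expect_equal(grads[[an$id]], w[, 1:2])
  expect_equal(grads[[bn$id]], w[, 5, drop = FALSE])
})

test_that("plain-matrix fast path agrees with the taped forward values", {
  ad <- asNamespace("molfm")
  set.seed(3)
  x <- matrix(rnorm(8), 4, 2)
  w <- matrix(rnorm(6), 2, 3)
  plain <- ad$ad_softmax_rows(ad$ad_matmul(x, w))
  tape <- ad$ad_tape()
  taped <- ad$ad_value(ad$ad_softmax_rows(ad$ad_matmul(ad$ad_leaf(tape, x),
                                                       ad$ad_leaf(tape, w))))
  expect_equal(plain, taped)
  expect_false(inherits(plain, "adnode"))
})

test_that("full network loss gradients match finite differences (both objectives)", {
  set.seed(4)
  mols <- generate_molecules(fixture_grammar(max_heavy = 3), 2)
  g1 <- mols[[1]]
  prior <- estimate_molecule_prior(mols, "marginal-simplex")
  g0 <- sample_molecule_prior(prior, g1$N, default_cb)
  pair <- conditional_pair(g0, g1)
  t <- 0.4
  ss <- schedule_set()
  gt <- interpolate_pair(pair, ss, t)
  for (objective in c("endpoint", "vector_field")) {
    m <- tiny_model(objective = objective)
    loss_of <- function(params) {
      out <- molfm:::model_forward(params, m$config, m$codebook, gt, t)
      as.numeric(molfm:::ad_value(
        molfm:::tape_loss(out, pair, gt, ss, t, objective, c(3, 0.4, 1, 2))))
    }
    tape <- molfm:::ad_tape()
    wp <- molfm:::wrap_params(tape, m$params)
    out <- molfm:::model_forward(wp, m$config, m$codebook, gt, t)
    loss <- molfm:::tape_loss(out, pair, gt, ss, t, objective, c(3, 0.4, 1, 2))
    grads <- molfm:::collect_grads(wp, molfm:::ad_backward(loss))
    flat_g <- unlist(grads)
    flat_p <- unlist(m$params)
    idx <- sample(length(flat_p), 12)
    for (i in idx) {
      eps <- 1e-6
      up <- flat_p; up[i] <- up[i] + eps
      dn <- flat_p; dn[i] <- dn[i] - eps
      num <- (loss_of(utils::relist(up, m$params)) -
                loss_of(utils::relist(dn, m$params))) / (2 * eps)
      expect_equal(flat_g[[i]], num, tolerance = 1e-4)
    }
  }
})

test_that("Adam decreases a quadratic objective", {
  ad <- asNamespace("molfm")
  set.seed(5)
  params <- list(w = matrix(rnorm(4), 2, 2))
  target <- matrix(c(1, 2, 3, 4), 2, 2)
  st <- ad$adam_state(params)
  vals <- numeric(50)
  for (k in 1:50) {
    grads <- list(w = 2 * (params$w - target))
    vals[k] <- sum((params$w - target)^2)
    res <- ad$adam_step(params, grads, st, lr = 0.1)
    params <- res$params; st <- res$state
  }
  expect_lt(vals[50], vals[1] / 10)
})
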