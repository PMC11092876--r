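# Shared fixtures built in code. Everything is deterministic given the seed
# set inside each test.

default_cb <- category_codebook()

# water: O at origin, two H, two single bonds
water_graph <- function(cb = default_cb) {
  X <- rbind(c(0, 0, 0), c(0.9572, 0, 0), c(-0.24, 0.9266, 0))
  bonds <- data.frame(i = c(1, 1), j = c(2, 3), order = "single",
                      stringsAsFactors = FALSE)
  encode_molecule(c("O", "H", "H"), c(0L, 0L, 0L), bonds, X, cb)
}

# methane-like single carbon with k hydrogens (k = 5 gives an invalid
# hypervalent carbon)
ch_k_graph <- function(k, cb = default_cb) {
  theta <- seq(0, 2 * pi, length.out = k + 1)[seq_len(k)]
  X <- rbind(c(0, 0, 0), cbind(cos(theta), sin(theta), 0.3))
  bonds <- data.frame(i = rep(1, k), j = 1 + seq_len(k), order = "single",
                      stringsAsFactors = FALSE)
  encode_molecule(c("C", rep("H", k)), rep(0L, k + 1), bonds, X, cb)
}

random_simplex_rows <- function(m, d) {
  x <- matrix(stats::rexp(m * d), m, d)
  x / rowSums(x)
}

# small random molecule graph with simplex-valued (not one-hot) rows
random_relaxed_graph <- function(n, cb = default_cb) {
  molecule_graph(matrix(stats::rnorm(n * 3), n, 3),
                 random_simplex_rows(n, cb$n_a),
                 random_simplex_rows(n, cb$n_c),
                 random_simplex_rows(n * (n - 1) / 2, cb$n_e),
                 cb, check = FALSE)
}

tiny_model <- function(..., cb = default_cb) {
  args <- utils::modifyList(list(codebook = cb, n_blocks = 1, scalar_dim = 8,
                                 vector_dim = 2, edge_dim = 6, rbf_dim = 4),
                            list(...))
  do.call(flowmol_model, args)
}

expect_rows_on_simplex <- function(m, tol = 1e-7) {
  expect_true(assert_on_simplex(m, tol = tol))
}

# fake model whose endpoint prediction is a constant molecule g_star; used
# to drive the sampler with a closed-form field
constant_endpoint_model <- function(g_star, schedules = schedule_set()) {
  structure(list(schedules = schedules,
                 config = list(objective = "endpoint"),
                 g_star = g_star),
            class = "fake_model")
}

# brute-force alignment oracle: every permutation, each with its own Kabsch
# fit (written independently of align_pair internals)
oracle_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  out <- NULL
  sub <- oracle_permutations(n - 1L)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  out
}

brute_force_alignment <- function(x0, x1) {
  n <- nrow(x0)
  perms <- oracle_permutations(n)
  best <- NULL
  for (k in seq_len(nrow(perms))) {
    p <- perms[k, ]
    h <- svd(crossprod(x0[p, , drop = FALSE], x1))
    d <- sign(det(h$v %*% t(h$u)))
    r <- h$u %*% diag(c(1, 1, d)) %*% t(h$v)
    cost <- sum((x0[p, , drop = FALSE] %*% r - x1)^2)
    if (is.null(best) || cost < best$cost) {
      best <- list(perm = p, rotation = r, cost = cost)
    }
  }
  best
}
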