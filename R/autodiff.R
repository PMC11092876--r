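# Minimal reverse-mode automatic differentiation on matrices.
#
# The deep-learning stacks this package's networks would normally ride on do
# not exist in the R environment, so training is powered by this small tape:
# every op either computes plainly (when no argument is a tape node; this is
# the zero-overhead inference path) or records a node with a closure that
# maps the output gradient to parent gradients. Values are numeric matrices
# throughout (scalars are 1 x 1). Gradients are checked against central
# finite differences in the test suite.

ad_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 512)
  e$n <- 0L
  e
}

is_ad <- function(x) inherits(x, "adnode")

ad_value <- function(x) if (is_ad(x)) x$value else x

ad_new <- function(tape, value, parents = integer(0), bw = NULL) {
  tape$n <- tape$n + 1L
  id <- tape$n
  if (id > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[id]] <- list(parents = parents, bw = bw)
  structure(list(value = value, id = id, tape = tape), class = "adnode")
}

ad_leaf <- function(tape, value) ad_new(tape, value)

tape_of <- function(...) {
  for (x in list(...)) if (is_ad(x)) return(x$tape)
  NULL
}

# run the backward pass from a scalar (1 x 1) node; returns a list of
# gradients indexed by node id (NULL where no gradient flowed)
ad_backward <- function(root) {
  tape <- root$tape
  grads <- vector("list", tape$n)
  grads[[root$id]] <- matrix(1, 1, 1)
  for (id in seq(root$id, 1L)) {
    g <- grads[[id]]
    node <- tape$nodes[[id]]
    if (is.null(g) || is.null(node$bw)) next
    pg <- node$bw(g)
    for (k in seq_along(node$parents)) {
      p <- node$parents[k]
      if (p == 0L || is.null(pg[[k]])) next
      grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
    }
  }
  grads
}

parent_id <- function(x) if (is_ad(x)) x$id else 0L

# ---- elementwise and linear-algebra ops --------------------------------

ad_add <- function(a, b) {
  tp <- tape_of(a, b)
  av <- ad_value(a); bv <- ad_value(b)
  if (is.null(tp)) return(av + bv)
  ad_new(tp, av + bv, c(parent_id(a), parent_id(b)),
         function(g) list(g, g))
}

ad_sub <- function(a, b) {
  tp <- tape_of(a, b)
  av <- ad_value(a); bv <- ad_value(b)
  if (is.null(tp)) return(av - bv)
  ad_new(tp, av - bv, c(parent_id(a), parent_id(b)),
         function(g) list(g, -g))
}

ad_mul <- function(a, b) {
  tp <- tape_of(a, b)
  av <- ad_value(a); bv <- ad_value(b)
  if (is.null(tp)) return(av * bv)
  ad_new(tp, av * bv, c(parent_id(a), parent_id(b)),
         function(g) list(g * bv, g * av))
}

ad_div <- function(a, b) {
  tp <- tape_of(a, b)
  av <- ad_value(a); bv <- ad_value(b)
  if (is.null(tp)) return(av / bv)
  ad_new(tp, av / bv, c(parent_id(a), parent_id(b)),
         function(g) list(g / bv, -g * av / bv^2))
}

# multiply / shift by a plain scalar constant
ad_smul <- function(a, s) {
  if (!is_ad(a)) return(ad_value(a) * s)
  ad_new(a$tape, a$value * s, a$id, function(g) list(g * s))
}

ad_adds <- function(a, s) {
  if (!is_ad(a)) return(ad_value(a) + s)
  ad_new(a$tape, a$value + s, a$id, function(g) list(g))
}

ad_matmul <- function(a, b) {
  tp <- tape_of(a, b)
  av <- ad_value(a); bv <- ad_value(b)
  if (is.null(tp)) return(av %*% bv)
  ad_new(tp, av %*% bv, c(parent_id(a), parent_id(b)),
         function(g) list(g %*% t(bv), t(av) %*% g))
}

# add a 1 x d bias row to every row of an n x d matrix
ad_addbias <- function(a, b) {
  tp <- tape_of(a, b)
  av <- ad_value(a); bv <- ad_value(b)
  if (is.null(tp)) return(sweep(av, 2, as.numeric(bv), "+"))
  ad_new(tp, sweep(av, 2, as.numeric(bv), "+"),
         c(parent_id(a), parent_id(b)),
         function(g) list(g, matrix(colSums(g), 1)))
}

ad_tanh <- function(a) {
  if (!is_ad(a)) return(tanh(ad_value(a)))
  y <- tanh(a$value)
  ad_new(a$tape, y, a$id, function(g) list(g * (1 - y^2)))
}

ad_sigmoid <- function(a) {
  sig <- function(x) 1 / (1 + exp(-x))
  if (!is_ad(a)) return(sig(ad_value(a)))
  y <- sig(a$value)
  ad_new(a$tape, y, a$id, function(g) list(g * y * (1 - y)))
}

ad_log <- function(a) {
  if (!is_ad(a)) return(log(ad_value(a)))
  v <- a$value
  ad_new(a$tape, log(v), a$id, function(g) list(g / v))
}

ad_sqrt <- function(a) {
  if (!is_ad(a)) return(sqrt(ad_value(a)))
  y <- sqrt(a$value)
  ad_new(a$tape, y, a$id, function(g) list(g / (2 * y)))
}

ad_sum <- function(a) {
  if (!is_ad(a)) return(matrix(sum(ad_value(a)), 1, 1))
  v <- a$value
  ad_new(a$tape, matrix(sum(v), 1, 1), a$id,
         function(g) list(matrix(as.numeric(g), nrow(v), ncol(v))))
}

# row-wise softmax; consumes and returns n x d
ad_softmax_rows <- function(a) {
  sm <- function(x) {
    y <- exp(x - apply(x, 1, max))
    y / rowSums(y)
  }
  if (!is_ad(a)) return(sm(ad_value(a)))
  y <- sm(a$value)
  ad_new(a$tape, y, a$id,
         function(g) list(y * (g - rowSums(g * y))))
}

# column-concatenation of nodes and/or plain matrices
ad_cbind <- function(...) {
  args <- list(...)
  tp <- do.call(tape_of, args)
  vals <- lapply(args, ad_value)
  if (is.null(tp)) return(do.call(cbind, vals))
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_new(tp, do.call(cbind, vals), vapply(args, parent_id, integer(1)),
         function(g) {
           lapply(seq_along(args), function(k) {
             g[, starts[k]:ends[k], drop = FALSE]
           })
         })
}

# gather rows: out = a[idx, ]; backward scatter-adds
ad_gather <- function(a, idx) {
  av <- ad_value(a)
  if (!is_ad(a)) return(av[idx, , drop = FALSE])
  n <- nrow(av); d <- ncol(av)
  ad_new(a$tape, av[idx, , drop = FALSE], a$id, function(g) {
    z <- matrix(0, n, d)
    if (length(idx) > 0) {
      rs <- rowsum(g, idx)
      z[as.integer(rownames(rs)), ] <- rs
    }
    list(z)
  })
}

# sum rows of a into ngroups buckets given by groups; backward gathers
ad_rowsum_by <- function(a, groups, ngroups) {
  av <- ad_value(a)
  fwd <- function(v) {
    z <- matrix(0, ngroups, ncol(v))
    if (nrow(v) > 0) {
      rs <- rowsum(v, groups)
      z[as.integer(rownames(rs)), ] <- rs
    }
    z
  }
  if (!is_ad(a)) return(fwd(av))
  ad_new(a$tape, fwd(av), a$id,
         function(g) list(g[groups, , drop = FALSE]))
}

# Gaussian radial basis expansion of a distance column (n x 1 -> n x k)
ad_rbf <- function(dist, centers, width) {
  dv <- ad_value(dist)
  k <- length(centers)
  fwd <- function(v) {
    if (nrow(v) == 0) return(matrix(numeric(0), 0, k))
    dm <- matrix(v, nrow(v), k)
    mu <- matrix(centers, nrow(v), k, byrow = TRUE)
    exp(-(dm - mu)^2 / width^2)
  }
  if (!is_ad(dist)) return(fwd(dv))
  if (nrow(dv) == 0) {
    return(ad_new(dist$tape, fwd(dv), dist$id,
                  function(g) list(matrix(numeric(0), 0, 1))))
  }
  y <- fwd(dv)
  dm <- matrix(dv, nrow(dv), k)
  mu <- matrix(centers, nrow(dv), k, byrow = TRUE)
  ad_new(dist$tape, y, dist$id, function(g) {
    list(matrix(rowSums(g * y * (-2 * (dm - mu) / width^2)), ncol = 1))
  })
}

# ---- parameter plumbing -------------------------------------------------

# wrap a nested list of parameter matrices into tape leaves (same shape)
wrap_params <- function(tape, params) {
  if (is.matrix(params)) return(ad_leaf(tape, params))
  lapply(params, wrap_params, tape = tape)
}

# read gradients for a nested structure of leaves out of ad_backward output
collect_grads <- function(nodes, grads) {
  if (is_ad(nodes)) {
    g <- grads[[nodes$id]]
    if (is.null(g)) g <- matrix(0, nrow(nodes$value), ncol(nodes$value))
    return(g)
  }
  lapply(nodes, collect_grads, grads = grads)
}

# ---- Adam optimizer over nested parameter lists -------------------------

adam_state <- function(params) {
  zero_like <- function(p) {
    if (is.matrix(p)) return(matrix(0, nrow(p), ncol(p)))
    lapply(p, zero_like)
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.matrix(p)) {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      return(list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v))
    }
    out <- Map(upd, p, g, m, v)
    list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
         v = lapply(out, `[[`, "v"))
  }
  res <- upd(params, grads, state$m, state$v)
  list(params = res$p, state = list(m = res$m, v = res$v, t = t))
}
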