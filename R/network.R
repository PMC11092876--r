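# Equivariant graph network predicting the destination molecule g1_hat.
#
# Feature layout inside the network:
#   * node positions       P: three n x 1 columns (x, y, z)
#   * node scalar features s: n x scalar_dim, rotation-invariant
#   * node vector features V: three n x vector_dim component matrices,
#     rotation order 1, initialized to zero
#   * directed edge features e: (2 * npair) x edge_dim; both directions
#     i->j and j->i exist for every unordered pair
# All geometry enters through interatomic differences, so the whole network
# commutes with global translation. Vector quantities are built from linear
# channel mixing, invariant gating, and (optionally) cross products of
# vector channels; cross products are rotation-equivariant but flip under
# reflection, which makes the model chirality-sensitive when enabled.

rand_mat <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(1 / max(1, nr))), nr, nc)
}

init_gvp <- function(ds_in, v_in, ds_out, v_out, h, cross) {
  # the vector path runs at twice the Xavier scale; the norm squash in
  # gvp_forward bounds the result, and at plain scale the cross-product
  # channels are numerically negligible (near-parallel small vectors)
  vscale <- 2
  p <- list(
    Wh = vscale * rand_mat(v_in, h),
    Ws = rand_mat(ds_in + h * (1 + cross), ds_out),
    bs = matrix(0, 1, ds_out),
    Wv = vscale * rand_mat(h * (1 + cross), v_out),
    Wg = rand_mat(ds_out, v_out),
    bg = matrix(0, 1, v_out))
  if (cross) p$Wu <- vscale * rand_mat(v_in, h)
  p
}

vec3 <- function(x, y, z) list(x = x, y = y, z = z)

vmap <- function(f, ...) {
  vs <- list(...)
  vec3(do.call(f, lapply(vs, `[[`, "x")),
       do.call(f, lapply(vs, `[[`, "y")),
       do.call(f, lapply(vs, `[[`, "z")))
}

vcross <- function(a, b) {
  vec3(ad_sub(ad_mul(a$y, b$z), ad_mul(a$z, b$y)),
       ad_sub(ad_mul(a$z, b$x), ad_mul(a$x, b$z)),
       ad_sub(ad_mul(a$x, b$y), ad_mul(a$y, b$x)))
}

vnorm <- function(v, eps = 1e-8) {
  ad_sqrt(ad_adds(ad_add(ad_add(ad_mul(v$x, v$x), ad_mul(v$y, v$y)),
                         ad_mul(v$z, v$z)), eps))
}

#' Geometric vector perceptron with optional cross-product channels
#'
#' Maps scalar features (n x ds_in) and geometric vector features (three
#' n x v_in component matrices) to updated scalars and vectors. Scalar
#' outputs depend on the vectors only through channel norms, so they are
#' invariant under global rotation; vector outputs are linear mixes of
#' rotated channels gated by invariant scalars, so they co-rotate. With
#' `cross = TRUE` an extra bank of channels is formed as cross products of
#' two learned channel mixes; these flip sign under reflection, breaking
#' mirror equivariance (the model becomes sensitive to chirality). With
#' `cross = FALSE` the layer is equivariant under the full orthogonal group
#' including reflections.
#'
#' @param params parameter list from the internal initializer.
#' @param s scalar features, n x ds_in (matrix or tape node).
#' @param v vector features, `vec3` list of n x v_in components.
#' @param cross include cross-product channels.
#' @return list with `s` (n x ds_out) and `v` (vec3 of n x v_out).
#' @keywords internal
gvp_forward <- function(params, s, v, cross) {
  vh <- vmap(function(m) ad_matmul(m, params$Wh), v)
  feats <- list(s, vnorm(vh))
  vcat <- vh
  if (cross) {
    vu <- vmap(function(m) ad_matmul(m, params$Wu), v)
    vc <- vcross(vh, vu)
    feats <- c(feats, list(vnorm(vc)))
    vcat <- vmap(ad_cbind, vh, vc)
  }
  s_out <- ad_tanh(ad_addbias(ad_matmul(do.call(ad_cbind, feats), params$Ws),
                              params$bs))
  v_mix <- vmap(function(m) ad_matmul(m, params$Wv), vcat)
  gate <- ad_sigmoid(ad_addbias(ad_matmul(s_out, params$Wg), params$bg))
  v_out <- vmap(function(m) ad_mul(m, gate), v_mix)
  # norm squash: rescale each vector channel by tanh(|v|)/|v|. Keeps
  # directions (so equivariance and chirality behavior are untouched) while
  # bounding channel norms, which lets the vector path run at a scale where
  # cross products are informative without positions blowing up block over
  # block.
  nrm <- vnorm(v_out)
  squash <- ad_div(ad_tanh(nrm), nrm)
  list(s = s_out, v = vmap(function(m) ad_mul(m, squash), v_out))
}

init_mlp <- function(d_in, d_hidden, d_out) {
  list(W1 = rand_mat(d_in, d_hidden), b1 = matrix(0, 1, d_hidden),
       W2 = rand_mat(d_hidden, d_out), b2 = matrix(0, 1, d_out))
}

mlp_forward <- function(p, x) {
  h <- ad_tanh(ad_addbias(ad_matmul(x, p$W1), p$b1))
  ad_addbias(ad_matmul(h, p$W2), p$b2)
}

#' Construct a molecule endpoint-prediction model
#'
#' The network embeds the current state g_t (with the time t appended to
#' every node's scalar features), refines it through `n_blocks` molecule
#' update blocks — each a node feature update (NFU, message passing over all
#' neighbors), a node position update (NPU, node-wise) and an edge feature
#' update (EFU, edge-wise) — and reads out predictions through shallow
#' node-wise and edge-wise MLPs. In endpoint mode the categorical heads end
#' in a softmax, so predicted atom-type/charge/bond rows lie exactly on
#' their simplices; bond predictions are made once per unordered pair from
#' the sum of the two directed edge features, hence invariant to the order
#' of the pair. In vector-field mode the heads are unconstrained tangents.
#'
#' @param codebook a [category_codebook()].
#' @param n_blocks number of molecule update blocks.
#' @param scalar_dim width of node scalar features.
#' @param vector_dim number of geometric vector channels per node.
#' @param edge_dim width of directed edge features.
#' @param rbf_dim number of Gaussian radial basis functions for distances.
#' @param rbf_max largest RBF center (Angstrom).
#' @param cross_products enable the chirality-sensitive cross-product
#'   channels (disable for a reflection-equivariant ablation).
#' @param objective `"endpoint"` or `"vector_field"`; controls the heads.
#' @param schedules [schedule_set()] stored with the model (used by the
#'   sampler and training loop).
#' @return object of class `flowmol_model` (parameters + config).
#' @export
flowmol_model <- function(codebook, n_blocks = 2, scalar_dim = 32,
                          vector_dim = 4, edge_dim = 16, rbf_dim = 8,
                          rbf_max = 4, cross_products = TRUE,
                          objective = c("endpoint", "vector_field"),
                          schedules = schedule_set()) {
  objective <- match.arg(objective)
  sd_ <- scalar_dim; vd <- vector_dim; ed <- edge_dim
  blocks <- lapply(seq_len(n_blocks), function(b) {
    list(
      # message GVP: scalars [s_i, s_j, e_ij, rbf], vectors [V_i, V_j, unit]
      msg = init_gvp(2 * sd_ + ed + rbf_dim, 2 * vd + 1, sd_, vd, vd + 1,
                     cross_products),
      # node update GVP on [s, agg_s] and [V, agg_V]
      upd = init_gvp(2 * sd_, 2 * vd, sd_, vd, vd, cross_products),
      # node-wise position update: one vector channel out
      npu = init_gvp(sd_, vd, sd_, 1, vd, cross_products),
      # edge-wise feature update MLP
      efu = list(W = rand_mat(ed + 2 * sd_ + rbf_dim, ed),
                 b = matrix(0, 1, ed)))
  })
  params <- list(
    embed_node = list(W = rand_mat(codebook$n_a + codebook$n_c + 1, sd_),
                      b = matrix(0, 1, sd_)),
    embed_edge = list(W = rand_mat(codebook$n_e + rbf_dim, ed),
                      b = matrix(0, 1, ed)),
    blocks = blocks,
    head_a = init_mlp(sd_, sd_, codebook$n_a),
    head_c = init_mlp(sd_, sd_, codebook$n_c),
    head_e = init_mlp(ed, ed, codebook$n_e))
  structure(list(
    params = params,
    config = list(n_blocks = n_blocks, scalar_dim = sd_, vector_dim = vd,
                  edge_dim = ed, rbf_dim = rbf_dim, rbf_max = rbf_max,
                  cross_products = cross_products, objective = objective),
    codebook = codebook,
    schedules = schedules),
    class = "flowmol_model")
}

#' @export
print.flowmol_model <- function(x, ...) {
  np <- sum(rapply(x$params, length, how = "unlist"))
  cat("flowmol_model:", x$config$n_blocks, "update blocks,",
      x$config$scalar_dim, "scalar /", x$config$vector_dim,
      "vector channels,", np, "parameters,",
      if (x$config$cross_products) "cross products on," else "cross products off,",
      x$config$objective, "objective\n")
  invisible(x)
}

# forward pass; params may be plain matrices (inference) or tape nodes
# (training). Returns heads prior to decoding.
model_forward <- function(params, cfg, codebook, g, t) {
  n <- g$N
  pairs <- pair_index(n)
  npair <- nrow(pairs)
  src <- c(pairs[, 1], pairs[, 2])
  dst <- c(pairs[, 2], pairs[, 1])
  centers <- seq(0, cfg$rbf_max, length.out = cfg$rbf_dim)
  width <- if (cfg$rbf_dim > 1) centers[2] - centers[1] else 1

  p_pos <- vec3(g$X[, 1, drop = FALSE], g$X[, 2, drop = FALSE],
                g$X[, 3, drop = FALSE])
  s <- ad_tanh(ad_addbias(
    ad_matmul(cbind(g$A, g$C, matrix(t, n, 1)), params$embed_node$W),
    params$embed_node$b))
  v <- vec3(matrix(0, n, cfg$vector_dim), matrix(0, n, cfg$vector_dim),
            matrix(0, n, cfg$vector_dim))

  edge_geom <- function(p_pos) {
    rel <- vmap(function(m) ad_sub(ad_gather(m, src), ad_gather(m, dst)),
                p_pos)
    dist <- vnorm(rel)
    list(rel = rel, dist = dist,
         unit = vmap(ad_div, rel, list(x = dist, y = dist, z = dist)),
         rbf = ad_rbf(dist, centers, width))
  }

  geo <- edge_geom(p_pos)
  e_dir <- ad_tanh(ad_addbias(
    ad_matmul(ad_cbind(rbind(g$E, g$E), geo$rbf), params$embed_edge$W),
    params$embed_edge$b))

  inv_nbrs <- 1 / max(1, n - 1)
  for (bp in params$blocks) {
    geo <- edge_geom(p_pos)
    # NFU: message passing over all neighbors
    ms <- ad_cbind(ad_gather(s, src), ad_gather(s, dst), e_dir, geo$rbf)
    mv <- vmap(ad_cbind,
               vmap(function(m) ad_gather(m, src), v),
               vmap(function(m) ad_gather(m, dst), v),
               geo$unit)
    msg <- gvp_forward(bp$msg, ms, mv, cfg$cross_products)
    agg_s <- ad_smul(ad_rowsum_by(msg$s, dst, n), inv_nbrs)
    agg_v <- vmap(function(m) ad_smul(ad_rowsum_by(m, dst, n), inv_nbrs),
                  msg$v)
    upd <- gvp_forward(bp$upd, ad_cbind(s, agg_s), vmap(ad_cbind, v, agg_v),
                       cfg$cross_products)
    s <- ad_add(s, upd$s)
    v <- vmap(ad_add, v, upd$v)
    # NPU: node-wise position update
    npu <- gvp_forward(bp$npu, s, v, cfg$cross_products)
    p_pos <- vmap(ad_add, p_pos, npu$v)
    # EFU: edge-wise feature update
    geo2 <- edge_geom(p_pos)
    e_in <- ad_cbind(e_dir, ad_gather(s, src), ad_gather(s, dst), geo2$rbf)
    e_dir <- ad_add(e_dir, ad_tanh(ad_addbias(ad_matmul(e_in, bp$efu$W),
                                              bp$efu$b)))
  }

  a_logit <- mlp_forward(params$head_a, s)
  c_logit <- mlp_forward(params$head_c, s)
  # one bond prediction per unordered pair, from the sum of both directions
  e_sum <- if (npair > 0) {
    ad_add(ad_gather(e_dir, seq_len(npair)),
           ad_gather(e_dir, npair + seq_len(npair)))
  } else {
    matrix(numeric(0), 0, cfg$edge_dim)
  }
  e_logit <- if (npair > 0) mlp_forward(params$head_e, e_sum) else
    matrix(numeric(0), 0, codebook$n_e)

  list(pos = p_pos, a = a_logit, c = c_logit, e = e_logit)
}

heads_to_graph <- function(out, g, objective, codebook) {
  X <- cbind(ad_value(out$pos$x), ad_value(out$pos$y), ad_value(out$pos$z))
  if (objective == "endpoint") {
    molecule_graph(X,
                   ad_value(ad_softmax_rows(out$a)),
                   ad_value(ad_softmax_rows(out$c)),
                   if (nrow(g$E) > 0) ad_value(ad_softmax_rows(out$e)) else g$E,
                   codebook, check = FALSE)
  } else {
    list(X = X - g$X, A = ad_value(out$a), C = ad_value(out$c),
         E = ad_value(out$e))
  }
}

#' Predict the destination molecule g1_hat
#'
#' Runs the network in endpoint mode on a state g_t. Categorical rows of the
#' prediction lie exactly on their simplices (softmax heads).
#'
#' @param model a [flowmol_model()] with endpoint objective.
#' @param g current state [molecule_graph()].
#' @param t time in \[0, 1\].
#' @return predicted [molecule_graph()] g1_hat.
#' @export
predict_endpoint <- function(model, g, t) {
  check_t(t)
  if (model$config$objective != "endpoint") {
    stop("model was built with the vector_field objective")
  }
  out <- model_forward(model$params, model$config, model$codebook, g, t)
  heads_to_graph(out, g, "endpoint", model$codebook)
}

#' Predict per-modality tangent vectors (vector-field objective)
#'
#' Unconstrained tangent predictions: the categorical components are raw
#' head outputs (no softmax), and the position component is the network's
#' position displacement (equivariant under rotation).
#'
#' @inheritParams predict_endpoint
#' @return list of tangent matrices `X`, `A`, `C`, `E`.
#' @export
predict_vf <- function(model, g, t) {
  check_t(t)
  if (model$config$objective != "vector_field") {
    stop("model was built with the endpoint objective")
  }
  out <- model_forward(model$params, model$config, model$codebook, g, t)
  heads_to_graph(out, g, "vector_field", model$codebook)
}
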