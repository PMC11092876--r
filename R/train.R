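# Training loops. Losses are rebuilt on the autodiff tape (mirroring the
# reference implementations in training_loss(), which the tests compare
# against) and parameters are updated with Adam.

# tape-based per-molecule loss; `out` are raw model heads for state g_t
tape_loss <- function(out, pair, g_t, schedules, t, objective, eta,
                      cross_entropy_eps = 1e-12) {
  g1 <- pair$g1
  n <- g1$N
  npair <- nrow(g1$E)
  sq <- function(a, b) ad_sum(ad_mul(d <- ad_sub(a, b), d))
  ce <- function(logits, target) {
    # mean cross-entropy of softmax rows against one-hot targets
    p <- ad_softmax_rows(logits)
    lp <- ad_log(ad_adds(p, cross_entropy_eps))
    ad_smul(ad_sum(ad_mul(lp, target)), -1 / nrow(target))
  }
  if (objective == "endpoint") {
    w <- vapply(c("X", "A", "C", "E"),
                function(m) loss_weight(schedules[[m]], t), numeric(1))
    lx <- ad_smul(ad_add(ad_add(sq(out$pos$x, g1$X[, 1, drop = FALSE]),
                                sq(out$pos$y, g1$X[, 2, drop = FALSE])),
                         sq(out$pos$z, g1$X[, 3, drop = FALSE])), 1 / n)
    la <- ce(out$a, g1$A)
    lc <- ce(out$c, g1$C)
    total <- ad_add(ad_add(ad_smul(lx, eta[1] * w[["X"]]),
                           ad_smul(la, eta[2] * w[["A"]])),
                    ad_smul(lc, eta[3] * w[["C"]]))
    if (npair > 0) {
      total <- ad_add(total, ad_smul(ce(out$e, g1$E), eta[4] * w[["E"]]))
    }
  } else {
    u <- conditional_vf(pair, schedules, t)
    vx <- ad_smul(ad_add(ad_add(
      sq(ad_sub(out$pos$x, g_t$X[, 1, drop = FALSE]), u$X[, 1, drop = FALSE]),
      sq(ad_sub(out$pos$y, g_t$X[, 2, drop = FALSE]), u$X[, 2, drop = FALSE])),
      sq(ad_sub(out$pos$z, g_t$X[, 3, drop = FALSE]), u$X[, 3, drop = FALSE])),
      1 / n)
    va <- ad_smul(sq(out$a, u$A), 1 / n)
    vc <- ad_smul(sq(out$c, u$C), 1 / n)
    total <- ad_add(ad_add(ad_smul(vx, eta[1]), ad_smul(va, eta[2])),
                    ad_smul(vc, eta[3]))
    if (npair > 0) {
      total <- ad_add(total, ad_smul(ad_smul(sq(out$e, u$E), 1 / npair),
                                     eta[4]))
    }
  }
  total
}

#' Train a molecule flow matching model
#'
#' Stochastic training on a set of one-hot data molecules: each step draws a
#' minibatch, pairs every data molecule with a fresh prior draw (optionally
#' OT-aligned), samples one t ~ U(0, 1) per molecule, interpolates to g_t,
#' and takes an Adam step on the weighted flow matching loss (endpoint or
#' vector-field, per the model's objective).
#'
#' @param model a [flowmol_model()].
#' @param mols list of one-hot, centered [molecule_graph()] training data.
#' @param prior a [molecule_prior_spec()].
#' @param steps number of optimizer steps.
#' @param batch_size molecules per step.
#' @param lr Adam learning rate.
#' @param ot apply optimal-transport alignment of prior to data positions.
#' @param eta per-modality loss weights (X, A, C, E).
#' @param flow_type `"linear"` draws g_t from the deterministic interpolant;
#'   `"dirichlet"` instead draws the categorical components of g_t from the
#'   Dirichlet conditional path around the data class (positions still
#'   interpolate). Dirichlet paths require a uniform-simplex categorical
#'   prior and the endpoint objective.
#' @param omega_max Dirichlet concentration cap (see
#'   [dirichlet_path_sample()]).
#' @param verbose print running loss every 50 steps.
#' @return list: `model` (trained), `loss` (numeric vector, one entry per
#'   step).
#' @export
train_flowmol <- function(model, mols, prior, steps = 200, batch_size = 8,
                          lr = 2e-3, ot = TRUE, eta = c(3, 0.4, 1, 2),
                          flow_type = c("linear", "dirichlet"),
                          omega_max = 100, verbose = FALSE) {
  flow_type <- match.arg(flow_type)
  if (flow_type == "dirichlet") {
    fams <- c(prior$a$family, prior$c$family, prior$e$family)
    if (any(fams != "uniform-simplex")) {
      stop("Dirichlet conditional paths require a uniform-simplex prior")
    }
    if (model$config$objective != "endpoint") {
      stop("Dirichlet conditional paths are used with the endpoint objective")
    }
  }
  params <- model$params
  state <- adam_state(params)
  cfg <- model$config
  cb <- model$codebook
  schedules <- model$schedules
  loss_hist <- numeric(steps)
  objective <- cfg$objective
  zero_like <- function(p) if (is.matrix(p)) p * 0 else lapply(p, zero_like)
  for (step in seq_len(steps)) {
    idx <- sample.int(length(mols), batch_size, replace = TRUE)
    gsum <- NULL
    lsum <- 0
    for (i in idx) {
      g1 <- mols[[i]]
      g0 <- sample_molecule_prior(prior, g1$N, cb)
      pair <- if (ot && g1$N > 1) ot_couple(g0, g1) else conditional_pair(g0, g1)
      t <- stats::runif(1)
      g_t <- interpolate_pair(pair, schedules, t)
      if (flow_type == "dirichlet") {
        g_t$A <- dirichlet_rows(pair$g1$A, t, schedules$A, omega_max)
        g_t$C <- dirichlet_rows(pair$g1$C, t, schedules$C, omega_max)
        if (nrow(g_t$E) > 0) {
          g_t$E <- dirichlet_rows(pair$g1$E, t, schedules$E, omega_max)
        }
      }
      tape <- ad_tape()
      wp <- wrap_params(tape, params)
      out <- model_forward(wp, cfg, cb, g_t, t)
      loss <- tape_loss(out, pair, g_t, schedules, t, objective, eta)
      lsum <- lsum + as.numeric(ad_value(loss))
      grads <- collect_grads(wp, ad_backward(loss))
      gsum <- if (is.null(gsum)) grads else {
        add_nested <- function(a, b) {
          if (is.matrix(a)) a + b else Map(add_nested, a, b)
        }
        add_nested(gsum, grads)
      }
    }
    scale_nested <- function(p, s) if (is.matrix(p)) p * s else
      lapply(p, scale_nested, s = s)
    res <- adam_step(params, scale_nested(gsum, 1 / batch_size), state, lr)
    params <- res$params
    state <- res$state
    loss_hist[step] <- lsum / batch_size
    if (verbose && step %% 50 == 0) {
      message(sprintf("step %d  loss %.4f", step,
                      mean(utils::tail(loss_hist[seq_len(step)], 50))))
    }
  }
  model$params <- params
  list(model = model, loss = loss_hist)
}

# draw each row from the Dirichlet conditional path of its one-hot target
dirichlet_rows <- function(target, t, schedule, omega_max) {
  classes <- argmax_rows(target)
  out <- matrix(0, nrow(target), ncol(target))
  for (cl in unique(classes)) {
    rows <- which(classes == cl)
    out[rows, ] <- dirichlet_path_sample(cl, ncol(target), t, schedule,
                                         m = length(rows),
                                         omega_max = omega_max)
  }
  out
}

# ---- toy categorical task: a single simplex-valued variable -------------

#' Small MLP endpoint model for a single categorical variable
#'
#' Desk-scale surrogate used to study simplex flows in isolation: maps a
#' point on (or near) the simplex plus the time t to a predicted endpoint
#' distribution via a two-hidden-layer tanh MLP with a softmax head.
#'
#' @param d number of categories.
#' @param hidden hidden width.
#' @param schedule an [interpolant_schedule()] for the single modality.
#' @return object of class `toy_simplex_model`.
#' @export
toy_simplex_model <- function(d, hidden = 64,
                              schedule = interpolant_schedule(1)) {
  params <- list(W1 = rand_mat(d + 1, hidden), b1 = matrix(0, 1, hidden),
                 W2 = rand_mat(hidden, hidden), b2 = matrix(0, 1, hidden),
                 W3 = rand_mat(hidden, d), b3 = matrix(0, 1, d))
  structure(list(params = params, d = d, schedule = schedule),
            class = "toy_simplex_model")
}

toy_forward <- function(params, x, t) {
  # x: m x d (matrix or node); t: length-m time column
  h1 <- ad_tanh(ad_addbias(ad_matmul(ad_cbind(x, matrix(t, nrow(ad_value(x)))),
                                     params$W1), params$b1))
  h2 <- ad_tanh(ad_addbias(ad_matmul(h1, params$W2), params$b2))
  ad_addbias(ad_matmul(h2, params$W3), params$b3)  # logits
}

#' Predict the endpoint distribution for toy simplex states
#' @param model a [toy_simplex_model()].
#' @param x m x d matrix of current states.
#' @param t time(s); scalar or length-m.
#' @return m x d matrix of simplex rows.
#' @export
toy_predict <- function(model, x, t) {
  t <- rep(t, length.out = nrow(x))
  ad_softmax_rows(toy_forward(model$params, x, t))
}

#' Train the toy simplex-flow model
#'
#' Endpoint-parameterized flow matching for one categorical variable: data
#' are one-hot rows (class frequencies q), the prior is any
#' [categorical_prior_spec()], and the loss is the w(t)-weighted
#' cross-entropy of the predicted endpoint against the data vertex, with t
#' drawn independently per row.
#'
#' @param model a [toy_simplex_model()].
#' @param x1 n x d one-hot data matrix (e.g. from [make_toy_task()]).
#' @param prior a [categorical_prior_spec()].
#' @param steps Adam steps.
#' @param batch_size rows per step.
#' @param lr learning rate.
#' @return list: `model`, `loss` (per-step numeric).
#' @export
train_toy <- function(model, x1, prior, steps = 1500, batch_size = 256,
                      lr = 2e-3) {
  params <- model$params
  state <- adam_state(params)
  d <- model$d
  sched <- model$schedule
  loss_hist <- numeric(steps)
  for (step in seq_len(steps)) {
    rows <- x1[sample.int(nrow(x1), batch_size, replace = TRUE), , drop = FALSE]
    x0 <- sample_categorical_prior(prior, batch_size, d)
    t <- stats::runif(batch_size)
    a <- schedule_alpha(sched, t)
    xt <- (1 - a) * x0 + a * rows
    w <- loss_weight(sched, t)
    tape <- ad_tape()
    wp <- wrap_params(tape, params)
    logits <- toy_forward(wp, xt, t)
    p <- ad_softmax_rows(logits)
    lp <- ad_log(ad_adds(p, 1e-12))
    # per-row weight: fold w(t) into the one-hot mask
    loss <- ad_smul(ad_sum(ad_mul(lp, rows * w)), -1 / batch_size)
    loss_hist[step] <- as.numeric(ad_value(loss))
    grads <- collect_grads(wp, ad_backward(loss))
    res <- adam_step(params, grads, state, lr)
    params <- res$params
    state <- res$state
  }
  model$params <- params
  list(model = model, loss = loss_hist)
}

#' Sample the toy simplex flow
#'
#' Vectorized Euler integration of the endpoint field for m independent
#' categorical variables, with the per-step weight clamped so simplex states
#' stay on the simplex.
#'
#' @param model a trained [toy_simplex_model()].
#' @param prior a [categorical_prior_spec()] (simplex-supported for
#'   guaranteed on-simplex trajectories).
#' @param m number of samples.
#' @param cfg a [sampling_config()].
#' @param trace keep intermediate states.
#' @return list: `classes` (argmax of the final endpoint prediction),
#'   `x` (final states), and `states` when `trace = TRUE`.
#' @export
sample_toy <- function(model, prior, m, cfg = sampling_config(),
                       trace = FALSE) {
  d <- model$d
  sched <- model$schedule
  x <- sample_categorical_prior(prior, m, d)
  ts <- seq(0, cfg$t_max, length.out = cfg$n_steps + 1)
  states <- if (trace) vector("list", cfg$n_steps + 1) else NULL
  if (trace) states[[1]] <- x
  pred <- NULL
  for (k in seq_len(cfg$n_steps)) {
    t <- ts[k]; dt <- ts[k + 1] - ts[k]
    pred <- toy_predict(model, x, t)
    a <- schedule_alpha(sched, t)
    w <- min(schedule_alpha_prime(sched, t) / (1 - a), 1 / dt)
    x <- x + dt * w * (pred - x)
    if (trace) states[[k + 1]] <- x
  }
  list(classes = argmax_rows(pred), x = x, states = states)
}
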