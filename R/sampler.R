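#' Sampling configuration
#'
#' @param n_steps number of Euler steps on an evenly spaced time grid
#'   (default 100; sample quality is known not to improve beyond that).
#' @param t_max terminal integration time, slightly below 1 so the endpoint
#'   field's `alpha'/(1 - alpha)` weight never divides by zero; the final
#'   categorical state is then set to the model's last endpoint prediction
#'   (a documented substitute for the unspecified terminal treatment).
#' @return object of class `sampling_config`.
#' @export
sampling_config <- function(n_steps = 100, t_max = 1 - 1e-4) {
  if (n_steps < 1) stop("n_steps must be >= 1")
  if (t_max <= 0 || t_max > 1) stop("t_max must lie in (0, 1]")
  structure(list(n_steps = as.integer(n_steps), t_max = t_max),
            class = "sampling_config")
}

#' Single Euler update of a molecule state
#'
#' `g' = g + dt * field` per modality, where `field` is a list of tangent
#' matrices `X`, `A`, `C`, `E` as produced by [conditional_vf()],
#' [endpoint_vf()] or [predict_vf()].
#'
#' @param g a [molecule_graph()].
#' @param field per-modality tangents.
#' @param dt positive step size.
#' @return the advanced `molecule_graph`.
#' @export
euler_step <- function(g, field, dt) {
  if (dt <= 0) stop("dt must be > 0")
  molecule_graph(g$X + dt * field$X, g$A + dt * field$A, g$C + dt * field$C,
                 g$E + dt * field$E, g$codebook, check = FALSE)
}

# endpoint field with per-modality clamp dt * alpha'/(1-alpha) <= 1, so each
# Euler update is a convex combination of state and predicted endpoint and
# simplex-valued states stay on the simplex
clamped_endpoint_field <- function(g, g1_hat, schedules, t, dt) {
  a <- modality_alpha(schedules, t)
  ap <- modality_alpha_prime(schedules, t)
  w <- pmin(ap / (1 - a), 1 / dt)
  list(X = w[["X"]] * (g1_hat$X - g$X),
       A = w[["A"]] * (g1_hat$A - g$A),
       C = w[["C"]] * (g1_hat$C - g$C),
       E = w[["E"]] * (g1_hat$E - g$E))
}

#' Integrate the learned ODE for one molecule
#'
#' Internal workhorse of [sample_molecules()]; exposed for tests. Advances a
#' prior sample g0 with `n_steps` Euler updates on the even grid
#' `[0, t_max]`. In endpoint mode the per-step weight is clamped so that
#' every update is a convex combination (simplex guarantee), and after the
#' last step the categorical modalities jump to the final endpoint
#' prediction while positions keep their integrated value.
#'
#' @param model a [flowmol_model()] (or any object honoring
#'   `predict_endpoint`/`predict_vf` via `predict_fn`).
#' @param g0 starting [molecule_graph()].
#' @param cfg a [sampling_config()].
#' @param predict_fn optional override: `function(g, t)` returning a
#'   molecule graph (endpoint mode) or tangents (vector-field mode); used to
#'   inject closed-form models in tests.
#' @param objective `"endpoint"` or `"vector_field"`; defaults to the
#'   model's objective.
#' @param trace if TRUE, also return the list of intermediate states.
#' @return final `molecule_graph` (one-hot categorical rows), or a list
#'   `list(final, states)` when `trace = TRUE`.
#' @export
integrate_flow <- function(model, g0, cfg = sampling_config(),
                           predict_fn = NULL, objective = NULL,
                           trace = FALSE) {
  schedules <- model$schedules
  if (is.null(objective)) objective <- model$config$objective
  if (is.null(predict_fn)) {
    predict_fn <- if (objective == "endpoint") {
      function(g, t) predict_endpoint(model, g, t)
    } else {
      function(g, t) predict_vf(model, g, t)
    }
  }
  ts <- seq(0, cfg$t_max, length.out = cfg$n_steps + 1)
  g <- g0
  states <- if (trace) vector("list", cfg$n_steps + 1) else NULL
  if (trace) states[[1]] <- g
  last_pred <- NULL
  for (k in seq_len(cfg$n_steps)) {
    t <- ts[k]
    dt <- ts[k + 1] - ts[k]
    field <- if (objective == "endpoint") {
      last_pred <- predict_fn(g, t)
      clamped_endpoint_field(g, last_pred, schedules, t, dt)
    } else {
      predict_fn(g, t)
    }
    g <- euler_step(g, field, dt)
    if (any(!vapply(list(g$X, g$A, g$C, g$E),
                    function(m) all(is.finite(m)), logical(1)))) {
      stop("non-finite state during integration")
    }
    if (trace) states[[k + 1]] <- g
  }
  if (objective == "endpoint" && !is.null(last_pred)) {
    # terminal jump: categorical modalities take the last endpoint
    # prediction; positions keep their integrated value
    g$A <- last_pred$A; g$C <- last_pred$C; g$E <- last_pred$E
  }
  if (trace) list(final = g, states = states) else g
}

#' Sample molecules from a trained model
#'
#' For each molecule: the atom count is drawn from the prior's empirical
#' histogram, a prior molecule g0 is sampled, the learned ODE is integrated
#' with Euler steps, and the final categorical rows are resolved to one-hot
#' by argmax. Molecules whose integration turns non-finite are dropped and
#' reported via the `n_failed` attribute.
#'
#' @param model a [flowmol_model()].
#' @param prior a [molecule_prior_spec()].
#' @param count number of molecules to generate.
#' @param cfg a [sampling_config()].
#' @return list of one-hot [molecule_graph()]; attribute `n_failed` counts
#'   aborted integrations.
#' @export
sample_molecules <- function(model, prior, count, cfg = sampling_config()) {
  cb <- model$codebook
  out <- vector("list", count)
  failed <- 0L
  for (k in seq_len(count)) {
    n <- sample_atom_count(prior$atom_count_hist)
    g0 <- sample_molecule_prior(prior, n, cb)
    g <- tryCatch(integrate_flow(model, g0, cfg), error = function(e) NULL)
    if (is.null(g)) {
      failed <- failed + 1L
      next
    }
    g$A <- to_onehot(argmax_rows(g$A), cb$n_a)
    g$C <- to_onehot(argmax_rows(g$C), cb$n_c)
    if (nrow(g$E) > 0) g$E <- to_onehot(argmax_rows(g$E), cb$n_e)
    out[[k]] <- g
  }
  out <- Filter(Negate(is.null), out)
  attr(out, "n_failed") <- failed
  out
}
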