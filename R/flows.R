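#' Conditional pair of prior and data molecules
#'
#' The conditioning variable of the conditional flow matching construction
#' is the pair of trajectory endpoints z = (g0, g1): a prior draw and a data
#' molecule with the same atom count and category dimensions.
#'
#' @param g0 prior [molecule_graph()].
#' @param g1 data [molecule_graph()].
#' @return object of class `conditional_pair`.
#' @export
conditional_pair <- function(g0, g1) {
  if (g0$N != g1$N) stop("g0 and g1 must have the same atom count")
  for (f in c("A", "C", "E")) {
    if (!identical(dim(g0[[f]]), dim(g1[[f]]))) {
      stop("category dimensions of g0 and g1 differ in ", f)
    }
  }
  structure(list(g0 = g0, g1 = g1, N = g1$N), class = "conditional_pair")
}

modality_alpha <- function(schedules, t) {
  vapply(c("X", "A", "C", "E"), function(m) schedule_alpha(schedules[[m]], t),
         numeric(1))
}

modality_alpha_prime <- function(schedules, t) {
  vapply(c("X", "A", "C", "E"),
         function(m) schedule_alpha_prime(schedules[[m]], t), numeric(1))
}

#' Interpolate a conditional pair
#'
#' Deterministic linear interpolant `g_t = (1 - alpha_t) g0 + alpha_t g1`,
#' applied per modality with that modality's schedule. Because the simplex
#' is closed under linear interpolation, categorical rows of g_t stay on the
#' simplex whenever both endpoints do.
#'
#' @param pair a [conditional_pair()].
#' @param schedules a [schedule_set()].
#' @param t time in \[0, 1\].
#' @return the interpolated [molecule_graph()] g_t.
#' @export
interpolate_pair <- function(pair, schedules, t) {
  check_t(t)
  a <- modality_alpha(schedules, t)
  g0 <- pair$g0; g1 <- pair$g1
  molecule_graph(
    X = (1 - a[["X"]]) * g0$X + a[["X"]] * g1$X,
    A = (1 - a[["A"]]) * g0$A + a[["A"]] * g1$A,
    C = (1 - a[["C"]]) * g0$C + a[["C"]] * g1$C,
    E = (1 - a[["E"]]) * g0$E + a[["E"]] * g1$E,
    codebook = g1$codebook, check = FALSE)
}

#' Conditional vector field of the linear interpolant
#'
#' The tangent of the conditional trajectory: `u = alpha'_t (g1 - g0)` per
#' modality. Equivalent, wherever alpha_t < 1, to the endpoint form
#' `(alpha'_t / (1 - alpha_t)) (g1 - g_t)`.
#'
#' @inheritParams interpolate_pair
#' @return list with per-modality tangent matrices `X`, `A`, `C`, `E`.
#' @export
conditional_vf <- function(pair, schedules, t) {
  ap <- modality_alpha_prime(schedules, t)
  g0 <- pair$g0; g1 <- pair$g1
  list(X = ap[["X"]] * (g1$X - g0$X),
       A = ap[["A"]] * (g1$A - g0$A),
       C = ap[["C"]] * (g1$C - g0$C),
       E = ap[["E"]] * (g1$E - g0$E))
}

#' Endpoint-parameterized vector field
#'
#' Reconstructs the velocity from a predicted endpoint:
#' `u = (alpha'_t / (1 - alpha_t)) (g1_hat - g_t)` per modality. When the
#' prediction's categorical rows lie on the simplex, Euler steps driven by
#' this field are convex combinations of the current state and the
#' prediction (for step sizes with `dt * alpha'/(1-alpha) <= 1`), which is
#' what keeps simplex flows on the simplex.
#'
#' @param g_t current state [molecule_graph()].
#' @param g1_hat predicted endpoint [molecule_graph()].
#' @param schedules a [schedule_set()].
#' @param t time in \[0, 1\]; every modality must have alpha_t < 1.
#' @return list with per-modality tangent matrices `X`, `A`, `C`, `E`.
#' @export
endpoint_vf <- function(g_t, g1_hat, schedules, t) {
  a <- modality_alpha(schedules, t)
  if (any(a >= 1 - 1e-12)) {
    stop("endpoint_vf undefined at alpha_t = 1; integrate to t_max < 1")
  }
  ap <- modality_alpha_prime(schedules, t)
  w <- ap / (1 - a)
  list(X = w[["X"]] * (g1_hat$X - g_t$X),
       A = w[["A"]] * (g1_hat$A - g_t$A),
       C = w[["C"]] * (g1_hat$C - g_t$C),
       E = w[["E"]] * (g1_hat$E - g_t$E))
}

# mean cross entropy of simplex-valued predictions against one-hot targets;
# consumes probabilities (softmax lives inside the model), not logits
cross_entropy_rows <- function(pred, target, eps = 1e-12) {
  if (nrow(pred) == 0) return(0)
  p <- pred[cbind(seq_len(nrow(pred)), argmax_rows(target))]
  mean(-log(pmax(p, eps)))
}

#' Per-molecule flow matching training loss
#'
#' Weighted combination of per-modality conditional flow matching losses,
#' `L = eta_X L_X + eta_A L_A + eta_C L_C + eta_E L_E`.
#'
#' Under the `"endpoint"` objective the model predicts the destination
#' molecule g1_hat and the loss is `w(t) * [squared error on X +
#' cross-entropy on A, C, E]` with the clamped weight `w(t)` of
#' [loss_weight()] (the raw weight `alpha'/(1-alpha)` is available via
#' `raw_weight = TRUE` for ablation). Under the `"vector_field"` objective
#' the prediction is a tangent and the loss is the squared error against
#' [conditional_vf()] for all modalities. Each modality term is a mean over
#' its rows, so the loss is invariant to consistent atom relabeling.
#'
#' @param pair a [conditional_pair()].
#' @param prediction for `"endpoint"`: a [molecule_graph()] g1_hat; for
#'   `"vector_field"`: a list with tangent matrices `X`, `A`, `C`, `E`.
#' @param schedules a [schedule_set()].
#' @param t the time at which g_t was drawn.
#' @param objective `"endpoint"` or `"vector_field"`.
#' @param eta length-4 weights (X, A, C, E); default `c(3, 0.4, 1, 2)`.
#' @param raw_weight use the unclamped endpoint weight (ablation only).
#' @return list with `total` and per-modality components `X`, `A`, `C`, `E`.
#' @export
training_loss <- function(pair, prediction, schedules, t,
                          objective = c("endpoint", "vector_field"),
                          eta = c(3, 0.4, 1, 2), raw_weight = FALSE) {
  objective <- match.arg(objective)
  stopifnot(length(eta) == 4)
  if (objective == "endpoint") {
    g1 <- pair$g1
    if (!inherits(prediction, "molecule_graph")) {
      stop("endpoint objective expects a molecule_graph prediction")
    }
    w <- vapply(c("X", "A", "C", "E"), function(m) {
      if (raw_weight) {
        a <- schedule_alpha(schedules[[m]], t)
        schedule_alpha_prime(schedules[[m]], t) / (1 - a)
      } else {
        loss_weight(schedules[[m]], t)
      }
    }, numeric(1))
    comp <- c(
      X = w[["X"]] * mean(rowSums((prediction$X - g1$X)^2)),
      A = w[["A"]] * cross_entropy_rows(prediction$A, g1$A),
      C = w[["C"]] * cross_entropy_rows(prediction$C, g1$C),
      E = if (nrow(g1$E) > 0) {
        w[["E"]] * cross_entropy_rows(prediction$E, g1$E)
      } else 0)
  } else {
    u <- conditional_vf(pair, schedules, t)
    if (!is.list(prediction) || !all(c("X", "A", "C", "E") %in% names(prediction))) {
      stop("vector_field objective expects a list of tangent matrices")
    }
    sqerr <- function(p, target) {
      if (length(target) == 0) return(0)
      mean(rowSums((p - target)^2))
    }
    comp <- c(X = sqerr(prediction$X, u$X), A = sqerr(prediction$A, u$A),
              C = sqerr(prediction$C, u$C), E = sqerr(prediction$E, u$E))
  }
  total <- sum(eta * comp)
  list(total = total, X = comp[["X"]], A = comp[["A"]], C = comp[["C"]],
       E = comp[["E"]])
}
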