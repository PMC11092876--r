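#' Cosine interpolant schedule
#'
#' The interpolant schedule controls the rate at which a prior sample is
#' transformed into a data sample along the conditional trajectory
#' `g_t = (1 - alpha_t) g0 + alpha_t g1`. The cosine family used here is
#'
#'   alpha(t) = 1 - cos^2((pi/2) * t^nu)
#'
#' which satisfies alpha(0) = 0, alpha(1) = 1 and is nondecreasing on
#' \[0, 1\] for any nu > 0. Each data modality (positions X, atom types A,
#' charges C, bonds E) carries its own schedule; see [schedule_set()].
#'
#' @param nu positive exponent; nu = 1 is the plain cosine schedule, larger
#'   nu delays the transformation toward t = 1.
#' @param kind schedule family; only `"cosine"` is implemented.
#' @param modality optional tag ("X", "A", "C" or "E"), bookkeeping only.
#' @return object of class `interpolant_schedule`.
#' @export
interpolant_schedule <- function(nu = 1, kind = "cosine", modality = NULL) {
  kind <- match.arg(kind, "cosine")
  if (!is.numeric(nu) || length(nu) != 1 || !is.finite(nu) || nu <= 0) {
    stop("nu must be a single positive number")
  }
  structure(list(nu = nu, kind = kind, modality = modality),
            class = "interpolant_schedule")
}

check_t <- function(t) {
  if (any(!is.finite(t)) || any(t < 0) || any(t > 1)) {
    stop("t must lie in [0, 1]")
  }
  t
}

#' Evaluate an interpolant schedule
#' @param s an [interpolant_schedule()].
#' @param t time(s) in \[0, 1\] (vectorized).
#' @return alpha(t) in \[0, 1\].
#' @export
schedule_alpha <- function(s, t) {
  check_t(t)
  1 - cos((pi / 2) * t^s$nu)^2
}

#' Time derivative of the interpolant schedule
#'
#' Closed form: alpha'(t) = (pi * nu / 2) * t^(nu - 1) * sin(pi * t^nu),
#' nonnegative on \[0, 1\]. The closed form is validated against central
#' finite differences in the test suite.
#'
#' @inheritParams schedule_alpha
#' @return alpha'(t) >= 0.
#' @export
schedule_alpha_prime <- function(s, t) {
  check_t(t)
  nu <- s$nu
  # t = 0 with nu < 1 is a 0 * Inf limit; the product t^(nu-1) * sin(pi t^nu)
  # behaves like pi * t^(2 nu - 1) -> 0 for nu > 1/2, -> pi/ (2) ... handle by
  # direct limit evaluation.
  out <- (pi * nu / 2) * t^(nu - 1) * sin(pi * t^nu)
  zero <- t == 0
  if (any(zero)) {
    out[zero] <- if (nu > 0.5) 0 else if (nu == 0.5) pi^2 / 4 else Inf
  }
  out
}

#' Clamped time-dependent training loss weight
#'
#' The endpoint objective's natural weight alpha'/(1 - alpha) blows up as
#' alpha -> 1; training instead uses
#' `w(t) = min(max(0.005, alpha_t / (1 - alpha_t)), 1.5)`, which is
#' nondecreasing in t and bounded in \[0.005, 1.5\].
#'
#' @inheritParams schedule_alpha
#' @return w(t) in \[0.005, 1.5\].
#' @export
loss_weight <- function(s, t) {
  a <- schedule_alpha(s, t)
  r <- ifelse(a >= 1, Inf, a / (1 - a))
  pmin(pmax(0.005, r), 1.5)
}

#' Per-modality schedule set
#'
#' One interpolant schedule per data modality. All four modalities share the
#' same sampled time t but may transform at different rates via nu.
#'
#' @param nu_x,nu_a,nu_c,nu_e cosine exponents for positions, atom types,
#'   charges and bond orders. Defaults are 1 for every modality (the
#'   per-modality exponents of the original large-scale models are not
#'   published; everything downstream is parameterized over nu).
#' @return object of class `schedule_set` with fields `X`, `A`, `C`, `E`.
#' @export
schedule_set <- function(nu_x = 1, nu_a = 1, nu_c = 1, nu_e = 1) {
  structure(list(X = interpolant_schedule(nu_x, modality = "X"),
                 A = interpolant_schedule(nu_a, modality = "A"),
                 C = interpolant_schedule(nu_c, modality = "C"),
                 E = interpolant_schedule(nu_e, modality = "E")),
            class = "schedule_set")
}

schedule_set_to_list <- function(ss) {
  list(nu_x = ss$X$nu, nu_a = ss$A$nu, nu_c = ss$C$nu, nu_e = ss$E$nu)
}

schedule_set_from_list <- function(x) {
  schedule_set(nu_x = x$nu_x, nu_a = x$nu_a, nu_c = x$nu_c, nu_e = x$nu_e)
}
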