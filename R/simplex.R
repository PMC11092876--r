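#' Test rows for membership of the probability simplex
#'
#' The d-dimensional probability simplex S_d is the set of nonnegative
#' vectors summing to 1; one-hot vectors are its vertices. Vertices are
#' admitted (the strict interior inequality is relaxed to >= 0) because
#' one-hot data lives exactly on the boundary.
#'
#' @param rows numeric matrix (or vector, treated as one row).
#' @param tol numeric tolerance on nonnegativity and the row sums.
#' @return `TRUE` iff every row is on the simplex within `tol`.
#' @export
assert_on_simplex <- function(rows, tol = 1e-9) {
  rows <- rbind(rows)
  if (nrow(rows) == 0) return(TRUE)
  if (any(!is.finite(rows))) return(FALSE)
  all(rows >= -tol) && all(abs(rowSums(rows) - 1) <= tol)
}

#' Euclidean projection onto the probability simplex
#'
#' Projects each row of a matrix onto S_d by the O(d log d) sort-based
#' algorithm (Held/Wolfe/Crowder): the projection of y is
#' `max(y - tau, 0)` where tau is chosen so the result sums to 1.
#' Idempotent and non-expansive.
#'
#' @param rows numeric matrix M x d with finite entries.
#' @return matrix of the same shape; every row on the simplex.
#' @export
project_to_simplex <- function(rows) {
  rows <- rbind(rows)
  if (any(!is.finite(rows))) stop("non-finite input to project_to_simplex")
  d <- ncol(rows)
  if (d == 1) return(matrix(1, nrow(rows), 1))
  # vectorized over rows: sort each row descending, find the pivot rho
  u <- t(apply(rows, 1, sort, decreasing = TRUE))
  css <- t(apply(u, 1, cumsum)) - 1
  k <- matrix(seq_len(d), nrow(rows), d, byrow = TRUE)
  cond <- u - css / k > 0
  rho <- apply(cond, 1, function(r) max(which(r)))
  tau <- css[cbind(seq_len(nrow(rows)), rho)] / rho
  out <- pmax(rows - tau, 0)
  dimnames(out) <- NULL
  out
}

#' Categorical prior specification
#'
#' Factorized prior families for a categorical modality living on (or, for
#' the Gaussian baseline, off) the probability simplex:
#' \describe{
#'   \item{uniform-simplex}{flat Dirichlet(1, ..., 1) over S_d.}
#'   \item{marginal-simplex}{one-hot vertices drawn with the empirical class
#'     probabilities `q`, then blurred and projected back.}
#'   \item{barycenter}{every row at the simplex center (1/d, ..., 1/d),
#'     then blurred and projected back.}
#'   \item{gaussian}{i.i.d. standard normal rows — the unconstrained
#'     baseline; no simplex invariant holds.}
#' }
#' Blurring adds N(0, blur_sigma^2) noise per coordinate before projection;
#' it widens degenerate priors whose support is a finite point set, which
#' otherwise cripples training.
#'
#' @param family one of `"gaussian"`, `"uniform-simplex"`,
#'   `"marginal-simplex"`, `"barycenter"`.
#' @param blur_sigma nonnegative blur standard deviation; only meaningful
#'   for the simplex families (default 0.15 for the degenerate families,
#'   ignored for gaussian).
#' @param q marginal class probabilities (marginal-simplex only); must lie
#'   on the simplex.
#' @return object of class `categorical_prior_spec`.
#' @export
categorical_prior_spec <- function(family = c("gaussian", "uniform-simplex",
                                              "marginal-simplex", "barycenter"),
                                   blur_sigma = 0.15, q = NULL) {
  family <- match.arg(family)
  if (!is.numeric(blur_sigma) || blur_sigma < 0) {
    stop("blur_sigma must be >= 0")
  }
  if (family == "marginal-simplex") {
    if (is.null(q)) stop("marginal-simplex prior requires marginals q")
    if (!assert_on_simplex(q, tol = 1e-8)) stop("q must lie on the simplex")
    q <- as.numeric(q)
  }
  structure(list(family = family, blur_sigma = blur_sigma, q = q),
            class = "categorical_prior_spec")
}

#' Sample a categorical prior
#'
#' @param spec a [categorical_prior_spec()].
#' @param m number of rows to draw.
#' @param d number of categories (for marginal-simplex, must equal
#'   `length(spec$q)`).
#' @return an M x d matrix. Simplex families return rows on S_d; the
#'   gaussian family returns unconstrained rows.
#' @export
sample_categorical_prior <- function(spec, m, d) {
  if (m == 0) return(matrix(numeric(0), 0, d))
  rows <- switch(spec$family,
    "gaussian" = matrix(stats::rnorm(m * d), m, d),
    "uniform-simplex" = rdirichlet(m, rep(1, d)),
    "marginal-simplex" = {
      if (length(spec$q) != d) stop("length(q) != d")
      to_onehot(sample.int(d, m, replace = TRUE, prob = spec$q), d)
    },
    "barycenter" = matrix(1 / d, m, d))
  if (spec$family %in% c("marginal-simplex", "barycenter") &&
      spec$blur_sigma > 0) {
    rows <- project_to_simplex(rows + matrix(stats::rnorm(m * d,
                                                          sd = spec$blur_sigma),
                                             m, d))
  }
  rows
}

# Dirichlet sampler via normalized gammas (base R has no rdirichlet)
rdirichlet <- function(m, gamma) {
  d <- length(gamma)
  x <- matrix(stats::rgamma(m * d, shape = rep(gamma, each = m)), m, d)
  x / rowSums(x)
}

#' Sample the Dirichlet conditional probability path
#'
#' The Dirichlet-flow conditional path for a d-categorical variable with
#' target class i is `Dir(gamma)` with `gamma = 1 + e_i * omega`, where the
#' concentration grows with time as `omega_t = omega_max * alpha_t + 1`.
#' At alpha_t = 0 this is Dirichlet with gamma_i = 2 (omega = 1); the path
#' converges to the vertex delta only in the limit omega -> infinity, so a
#' finite `omega_max` cap is explicit (default 100).
#'
#' @param class_index target class i in `[1, d]`.
#' @param d number of categories.
#' @param t time in \[0, 1\].
#' @param schedule an [interpolant_schedule()] supplying alpha_t.
#' @param m number of samples.
#' @param omega_max positive cap on the concentration growth.
#' @return M x d matrix of rows on the simplex.
#' @export
dirichlet_path_sample <- function(class_index, d, t, schedule, m = 1,
                                  omega_max = 100) {
  class_index <- as.integer(class_index)
  if (class_index < 1 || class_index > d) stop("class index out of range")
  if (omega_max <= 0) stop("omega_max must be > 0")
  a <- schedule_alpha(schedule, t)
  omega <- omega_max * a + 1
  gamma <- rep(1, d)
  gamma[class_index] <- 1 + omega
  rdirichlet(m, gamma)
}

#' Dirichlet path concentration parameter
#'
#' Deterministic companion to [dirichlet_path_sample()]; exposed for tests
#' and diagnostics.
#' @inheritParams dirichlet_path_sample
#' @return the concentration vector gamma.
#' @export
dirichlet_path_gamma <- function(class_index, d, t, schedule, omega_max = 100) {
  a <- schedule_alpha(schedule, t)
  gamma <- rep(1, d)
  gamma[class_index] <- 1 + omega_max * a + 1
  gamma
}
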