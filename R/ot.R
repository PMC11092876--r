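#' Kabsch superposition
#'
#' Proper rotation (det = +1, no reflection) minimizing the RMSD of `p` onto
#' `q` about the origin: both clouds are assumed centered. Reflections are
#' excluded deliberately — the downstream model is chirality-sensitive, so
#' alignment must not mirror prior samples.
#'
#' @param p,q centered N x 3 position matrices (p is rotated onto q).
#' @return 3 x 3 proper rotation matrix `R` such that `p %*% R` best fits `q`.
#' @export
kabsch_rotation <- function(p, q) {
  h <- crossprod(p, q)  # t(p) %*% q
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  # maximize tr(R^T H): R = U diag(1, 1, d) V^T, d correcting any reflection
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

alignment_cost <- function(p, q) sum((p - q)^2)

# assignment minimizing sum_i ||x0[perm[i],] - x1[i,]||^2 ; returns perm
optimal_assignment <- function(x0, x1) {
  n <- nrow(x0)
  if (n == 1) return(1L)
  # cost[i, j] = ||x0_i - x1_j||^2 ; solve_LSAP returns column for each row,
  # i.e. sigma with x0_i matched to x1_sigma(i); we need the inverse view.
  cost <- outer(rowSums(x0^2), rep(1, n)) + outer(rep(1, n), rowSums(x1^2)) -
    2 * x0 %*% t(x1)
  cost <- pmax(cost, 0)
  sigma <- as.integer(clue::solve_LSAP(cost))
  perm <- integer(n)
  perm[sigma] <- seq_len(n)  # perm[i] = which x0 row lands on x1 row i
  perm
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
  dimnames(out) <- NULL
  out
}

#' Optimal-transport alignment of two point clouds
#'
#' Finds the atom permutation and proper rigid rotation minimizing the sum
#' of squared distances between a prior point cloud `x0` and its paired data
#' cloud `x1` (both in the center-of-mass-free subspace). The permutation
#' `perm` and rotation `R` are to be applied to the prior cloud:
#' `x0[perm, ] %*% R` approximates `x1`.
#'
#' Methods: `"exact"` enumerates every permutation, fitting a Kabsch
#' rotation to each (global optimum; feasible for small N);
#' `"alternating"` iterates linear assignment and Kabsch from several
#' rotation starts until the cost stops decreasing (standard point-cloud OT
#' practice, but a local search); `"assign_once"` solves the assignment a
#' single time and then fits one rotation. `"auto"` (default) uses exact
#' search for N <= 7 and the alternating method above.
#'
#' @param x0 prior positions N x 3.
#' @param x1 data positions N x 3.
#' @param method see above.
#' @param max_rounds cap on assignment/Kabsch alternations per start.
#' @param n_starts number of random-rotation restarts for the alternating
#'   method (identity start is always included).
#' @param tol stop alternating when the cost improvement drops below this.
#' @return list of class `alignment_result`: `perm` (bijection on 1:N),
#'   `rotation` (3 x 3, det +1), `cost` (sum of squared residuals).
#' @export
align_pair <- function(x0, x1,
                       method = c("auto", "exact", "alternating", "assign_once"),
                       max_rounds = 10, n_starts = 8, tol = 1e-10) {
  method <- match.arg(method)
  x0 <- as.matrix(x0); x1 <- as.matrix(x1)
  n <- nrow(x0)
  if (nrow(x1) != n) stop("point clouds differ in size")
  if (max(abs(colMeans(x0))) > 1e-6 || max(abs(colMeans(x1))) > 1e-6) {
    warning("inputs not centered; centering internally")
    x0 <- center_positions(x0); x1 <- center_positions(x1)
  }
  if (method == "auto") method <- if (n <= 7) "exact" else "alternating"

  fit_perm <- function(perm) {
    p <- x0[perm, , drop = FALSE]
    r <- kabsch_rotation(p, x1)
    list(perm = perm, rotation = r, cost = alignment_cost(p %*% r, x1))
  }

  best <- switch(method,
    "exact" = {
      perms <- all_permutations(n)
      b <- fit_perm(perms[1, ])
      if (nrow(perms) > 1) {
        for (k in 2:nrow(perms)) {
          f <- fit_perm(perms[k, ])
          if (f$cost < b$cost) b <- f
        }
      }
      b
    },
    "assign_once" = fit_perm(optimal_assignment(x0, x1)),
    "alternating" = {
      starts <- c(list(diag(3)), lapply(seq_len(max(0, n_starts - 1)),
                                        function(i) random_rotation()))
      b <- NULL
      for (r0 in starts) {
        r <- r0
        prev <- Inf
        fit <- NULL
        for (round in seq_len(max_rounds)) {
          perm <- optimal_assignment(x0 %*% r, x1)
          fit <- fit_perm(perm)
          r <- fit$rotation
          if (prev - fit$cost < tol) break
          prev <- fit$cost
        }
        if (is.null(b) || fit$cost < b$cost) b <- fit
      }
      b
    })
  structure(best, class = "alignment_result")
}

#' Random proper rotation (Haar-ish via QR of a Gaussian matrix)
#' @return 3 x 3 rotation with det +1.
#' @export
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  d <- diag(sign(diag(qr.R(qr_))))
  q <- q %*% d
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Apply an alignment to the prior side of a conditional pair
#'
#' Reorders the prior molecule's atoms by the alignment permutation
#' (reindexing atom-type and charge rows and bond pair-rows consistently)
#' and rotates its positions. The data molecule g1 is left untouched, so the
#' target distribution is unchanged.
#'
#' @param pair a [conditional_pair()].
#' @param result an [align_pair()] result computed from this pair's
#'   positions.
#' @return the aligned `conditional_pair`.
#' @export
apply_alignment <- function(pair, result) {
  if (length(result$perm) != pair$N) stop("alignment size mismatch")
  g0 <- permute_molecule(pair$g0, result$perm)
  g0$X <- g0$X %*% result$rotation
  conditional_pair(g0, pair$g1)
}

#' Align and couple a prior molecule to a data molecule
#'
#' Convenience wrapper: computes [align_pair()] on the positions and applies
#' it, returning the aligned [conditional_pair()].
#'
#' @param g0 prior molecule; @param g1 data molecule.
#' @param ... passed to [align_pair()].
#' @export
ot_couple <- function(g0, g1, ...) {
  pair <- conditional_pair(g0, g1)
  if (g0$N == 1) return(pair)
  res <- align_pair(g0$X, g1$X, ...)
  apply_alignment(pair, res)
}
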