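#' Molecular graph container
#'
#' A molecule with `N` atoms is a fully connected attributed graph
#' `g = (X, A, C, E)`: positions `X` (N x 3, Angstrom), atom types `A`
#' (N x n_a), formal charges `C` (N x n_c) and bond orders `E` over all
#' unordered atom pairs ((N^2 - N)/2 x n_e). Categorical rows live on the
#' probability simplex; at data endpoints (t = 1) they are one-hot. Pairs
#' are enumerated in lexicographic order (1,2), (1,3), ..., (N-1,N); the
#' explicit "none" bond category makes the pair set total.
#'
#' @param X numeric matrix N x 3 of atom positions.
#' @param A numeric matrix N x n_a of atom-type rows.
#' @param C numeric matrix N x n_c of formal-charge rows.
#' @param E numeric matrix (N^2-N)/2 x n_e of bond-order rows, one per
#'   unordered pair in [pair_index()] order.
#' @param codebook a [category_codebook()] fixing the category axes.
#' @param check validate simplex membership of the categorical rows.
#'
#' @return An object of class `molecule_graph`.
#' @export
molecule_graph <- function(X, A, C, E, codebook, check = TRUE) {
  X <- as.matrix(X); A <- as.matrix(A); C <- as.matrix(C); E <- as.matrix(E)
  n <- nrow(X)
  if (ncol(X) != 3) stop("X must have 3 columns")
  if (nrow(A) != n || nrow(C) != n) stop("A and C must have one row per atom")
  if (ncol(A) != codebook$n_a) stop("A has ", ncol(A), " columns; codebook has ",
                                    codebook$n_a, " elements")
  if (ncol(C) != codebook$n_c) stop("C column count does not match codebook charges")
  if (ncol(E) != codebook$n_e) stop("E column count does not match codebook bond orders")
  npair <- n * (n - 1L) / 2L
  if (nrow(E) != npair) {
    stop("E must have (N^2-N)/2 = ", npair, " rows, got ", nrow(E))
  }
  g <- structure(list(X = X, A = A, C = C, E = E, N = n, codebook = codebook),
                 class = "molecule_graph")
  if (check) validate_molecule_graph(g)
  g
}

validate_molecule_graph <- function(g, tol = 1e-6) {
  for (f in c("A", "C")) {
    m <- g[[f]]
    if (any(!is.finite(m))) stop("non-finite entries in ", f)
  }
  if (any(!is.finite(g$X))) stop("non-finite entries in X")
  if (any(!is.finite(g$E))) stop("non-finite entries in E")
  invisible(g)
}

#' @export
print.molecule_graph <- function(x, ...) {
  onehot <- all(vapply(list(x$A, x$C, x$E), function(m) {
    nrow(m) == 0 || all(abs(m - round(m)) < 1e-9)
  }, logical(1)))
  cat("molecule_graph:", x$N, "atoms,", nrow(x$E), "pair rows",
      if (onehot) "(one-hot)" else "(relaxed)", "\n")
  if (x$N > 0 && onehot) {
    el <- x$codebook$elements[max.col(x$A, ties.method = "first")]
    cat("  formula:", paste0(names(table(el)), table(el), collapse = ""), "\n")
  }
  invisible(x)
}

#' Unordered pair enumeration for an N-atom graph
#'
#' @param n atom count.
#' @return integer matrix with columns `i`, `j` (i < j), one row per pair,
#'   in the canonical lexicographic order used by `molecule_graph$E`.
#' @examples
#' pair_index(3)  # rows (1,2), (1,3), (2,3)
#' @export
pair_index <- function(n) {
  n <- as.integer(n)
  if (n < 2) return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  m <- t(utils::combn(n, 2L))
  colnames(m) <- c("i", "j")
  m
}

#' Row of the pair (i, j) in the canonical enumeration
#' @param i,j atom indices (any order, i != j).
#' @param n atom count.
#' @return integer row index into `pair_index(n)`.
#' @export
pair_row <- function(i, j, n) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  if (any(lo == hi)) stop("pair indices must be distinct")
  if (any(hi > n) || any(lo < 1)) stop("pair index out of range")
  as.integer((lo - 1) * (2 * n - lo) / 2 + (hi - lo))
}

#' One-hot encode integer labels onto the probability simplex
#'
#' @param labels integer vector with values in `[1, d]` (1-based categories).
#' @param d number of categories.
#' @return numeric matrix `length(labels) x d`; each row one-hot.
#' @examples
#' to_onehot(c(3, 2), 3)
#' @export
to_onehot <- function(labels, d) {
  labels <- as.integer(labels)
  if (length(labels) == 0) return(matrix(numeric(0), ncol = d))
  if (any(labels < 1L | labels > d)) {
    stop("labels must lie in [1, ", d, "]")
  }
  m <- matrix(0, nrow = length(labels), ncol = d)
  m[cbind(seq_along(labels), labels)] <- 1
  m
}

# argmax with ties broken toward the lowest category index
argmax_rows <- function(m) {
  if (nrow(m) == 0) return(integer(0))
  max.col(m, ties.method = "first")
}

#' Decode a (possibly relaxed) molecule graph to discrete labels
#'
#' Resolves every categorical row by argmax (ties toward the lowest category
#' index), drops pairs whose argmax bond order is "none", and returns the
#' discrete molecule description used by the SDF writer and the metrics.
#' Rows need not be one-hot; this is the terminal decoding step of sampling.
#'
#' @param g a [molecule_graph()].
#' @return a list of class `decoded_molecule`: `elements`, `charges`
#'   (integers), `bonds` (data.frame `i`, `j`, `order` label), `X` positions.
#' @export
decode_molecule <- function(g) {
  cb <- g$codebook
  el <- cb$elements[argmax_rows(g$A)]
  ch <- cb$charges[argmax_rows(g$C)]
  pairs <- pair_index(g$N)
  ord <- cb$bond_orders[argmax_rows(g$E)]
  keep <- which(ord != "none")
  bonds <- data.frame(i = pairs[keep, "i"], j = pairs[keep, "j"],
                      order = ord[keep], stringsAsFactors = FALSE)
  structure(list(elements = el, charges = ch, bonds = bonds, X = g$X,
                 codebook = cb),
            class = "decoded_molecule")
}

#' Build a one-hot molecule graph from discrete labels
#'
#' Inverse of [decode_molecule()] for fully specified molecules: any pair
#' not listed in `bonds` receives a one-hot "none" row.
#'
#' @param elements character vector of element symbols.
#' @param charges integer vector of formal charges (defaults to all 0).
#' @param bonds data.frame with columns `i`, `j`, `order` (bond label).
#' @param X positions N x 3 (defaults to zeros).
#' @param codebook a [category_codebook()].
#' @return a one-hot [molecule_graph()].
#' @export
encode_molecule <- function(elements, charges = NULL, bonds = NULL, X = NULL,
                            codebook = category_codebook()) {
  n <- length(elements)
  if (is.null(charges)) charges <- rep(0L, n)
  if (is.null(X)) X <- matrix(0, n, 3)
  ei <- match(elements, codebook$elements)
  if (anyNA(ei)) stop("element not in codebook: ",
                      paste(unique(elements[is.na(ei)]), collapse = ", "))
  ci <- match(as.integer(charges), codebook$charges)
  if (anyNA(ci)) stop("charge not in codebook: ",
                      paste(unique(charges[is.na(ci)]), collapse = ", "))
  A <- to_onehot(ei, codebook$n_a)
  C <- to_onehot(ci, codebook$n_c)
  npair <- n * (n - 1L) / 2L
  none_idx <- match("none", codebook$bond_orders)
  elab <- rep(none_idx, npair)
  if (!is.null(bonds) && nrow(bonds) > 0) {
    oi <- match(bonds$order, codebook$bond_orders)
    if (anyNA(oi)) stop("bond order not in codebook: ",
                        paste(unique(bonds$order[is.na(oi)]), collapse = ", "))
    elab[pair_row(bonds$i, bonds$j, n)] <- oi
  }
  E <- to_onehot(elab, codebook$n_e)
  molecule_graph(X, A, C, E, codebook)
}

#' Reindex the atoms of a molecule graph
#'
#' Applies a permutation to the atom ordering, reindexing `X`, `A`, `C` rows
#' and the pair rows of `E` consistently: the pair \{i, j\} follows its atoms.
#'
#' @param g a [molecule_graph()].
#' @param perm integer permutation of `1:N`; atom `perm[k]` of `g` becomes
#'   atom `k` of the result.
#' @return the permuted `molecule_graph`.
#' @export
permute_molecule <- function(g, perm) {
  n <- g$N
  perm <- as.integer(perm)
  if (length(perm) != n || anyNA(perm) || !setequal(perm, seq_len(n))) {
    stop("perm must be a permutation of 1:", n)
  }
  pairs <- pair_index(n)
  # pair k of the output holds atoms (perm[i_k], perm[j_k]) of the input
  src <- pair_row(perm[pairs[, "i"]], perm[pairs[, "j"]], n)
  molecule_graph(g$X[perm, , drop = FALSE], g$A[perm, , drop = FALSE],
                 g$C[perm, , drop = FALSE], g$E[src, , drop = FALSE],
                 g$codebook, check = FALSE)
}

#' Center atom positions at zero centroid
#'
#' Projects positions into the center-of-mass-free subspace in which both
#' the prior and the data distribution are defined.
#'
#' @param g a [molecule_graph()].
#' @return `g` with `colMeans(X) == 0`.
#' @export
center_molecule <- function(g) {
  g$X <- center_positions(g$X)
  g
}

center_positions <- function(X) {
  sweep(X, 2, colMeans(X), "-")
}
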