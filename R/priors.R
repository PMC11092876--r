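#' Full molecule prior specification
#'
#' The molecule prior factorizes over atoms and atom pairs: positions are
#' i.i.d. standard Gaussian (then centered into the center-of-mass-free
#' subspace), and atom types, charges and bond orders are sampled
#' independently from their categorical prior specs. The atom count is drawn
#' from an empirical histogram, normally estimated from a reference set.
#'
#' For the marginal-simplex family the element and charge marginals are
#' treated jointly: the empirical joint (element, charge) distribution is
#' sampled and then split into the two one-hot rows, so correlated
#' element/charge combinations are respected.
#'
#' @param a_spec,c_spec,e_spec [categorical_prior_spec()] for atom types,
#'   charges and bond orders.
#' @param atom_count_hist named numeric vector: names are atom counts,
#'   values their probabilities (must sum to 1). See
#'   [atom_count_histogram()].
#' @param ac_joint optional matrix n_a x n_c of joint (element, charge)
#'   probabilities; used instead of independent a/c draws when both specs
#'   are marginal-simplex.
#' @return object of class `molecule_prior_spec`.
#' @export
molecule_prior_spec <- function(a_spec, c_spec, e_spec, atom_count_hist,
                                ac_joint = NULL) {
  stopifnot(inherits(a_spec, "categorical_prior_spec"),
            inherits(c_spec, "categorical_prior_spec"),
            inherits(e_spec, "categorical_prior_spec"))
  if (length(atom_count_hist) == 0) stop("atom count histogram is empty")
  if (abs(sum(atom_count_hist) - 1) > 1e-8) {
    stop("atom count histogram must sum to 1")
  }
  if (any(as.integer(names(atom_count_hist)) < 1)) {
    stop("atom count histogram must support N >= 1")
  }
  if (!is.null(ac_joint) && abs(sum(ac_joint) - 1) > 1e-8) {
    stop("ac_joint must sum to 1")
  }
  structure(list(a = a_spec, c = c_spec, e = e_spec,
                 atom_count_hist = atom_count_hist, ac_joint = ac_joint),
            class = "molecule_prior_spec")
}

#' Empirical atom-count histogram of a molecule set
#' @param mols list of [molecule_graph()].
#' @return named numeric probability vector over observed atom counts.
#' @export
atom_count_histogram <- function(mols) {
  if (length(mols) == 0) stop("empty molecule set")
  counts <- table(vapply(mols, function(g) g$N, numeric(1)))
  h <- as.numeric(counts) / sum(counts)
  names(h) <- names(counts)
  h
}

#' Draw an atom count from an empirical histogram
#' @param hist named probability vector as from [atom_count_histogram()].
#' @return a single positive integer.
#' @export
sample_atom_count <- function(hist) {
  if (length(hist) == 0) stop("empty atom count histogram")
  as.integer(sample(names(hist), 1, prob = hist))
}

#' Sample a molecule from the prior
#'
#' Positions are N(0, I) per atom, centered to zero centroid; categorical
#' rows are drawn independently from their specs (jointly for element and
#' charge when an `ac_joint` table is present and both families are
#' marginal-simplex).
#'
#' @param spec a [molecule_prior_spec()].
#' @param n atom count (N >= 1).
#' @param codebook a [category_codebook()] fixing category dimensions.
#' @return a [molecule_graph()]; positions have zero centroid.
#' @export
sample_molecule_prior <- function(spec, n, codebook) {
  n <- as.integer(n)
  if (n < 1) stop("atom count must be >= 1")
  X <- center_positions(matrix(stats::rnorm(n * 3), n, 3))
  use_joint <- !is.null(spec$ac_joint) &&
    spec$a$family == "marginal-simplex" && spec$c$family == "marginal-simplex"
  if (use_joint) {
    flat <- sample.int(length(spec$ac_joint), n, replace = TRUE,
                       prob = as.numeric(spec$ac_joint))
    ai <- (flat - 1L) %% nrow(spec$ac_joint) + 1L
    ci <- (flat - 1L) %/% nrow(spec$ac_joint) + 1L
    A <- to_onehot(ai, codebook$n_a)
    C <- to_onehot(ci, codebook$n_c)
    blur <- function(m, sigma) {
      if (sigma > 0) {
        project_to_simplex(m + matrix(stats::rnorm(length(m), sd = sigma),
                                      nrow(m), ncol(m)))
      } else m
    }
    A <- blur(A, spec$a$blur_sigma)
    C <- blur(C, spec$c$blur_sigma)
  } else {
    A <- sample_categorical_prior(spec$a, n, codebook$n_a)
    C <- sample_categorical_prior(spec$c, n, codebook$n_c)
  }
  E <- sample_categorical_prior(spec$e, n * (n - 1L) / 2L, codebook$n_e)
  molecule_graph(X, A, C, E, codebook, check = FALSE)
}

#' Estimate a molecule prior from a reference molecule set
#'
#' Convenience constructor: builds the atom-count histogram and, for
#' marginal-simplex families, the empirical marginals (joint for element and
#' charge, per-pair for bond orders) from a set of one-hot reference
#' molecules.
#'
#' @param mols list of one-hot [molecule_graph()] (e.g. training data).
#' @param family prior family for all three categorical modalities.
#' @param blur_sigma blur width for degenerate simplex families.
#' @return a [molecule_prior_spec()].
#' @export
estimate_molecule_prior <- function(mols,
                                    family = c("gaussian", "uniform-simplex",
                                               "marginal-simplex", "barycenter"),
                                    blur_sigma = 0.15) {
  family <- match.arg(family)
  if (length(mols) == 0) stop("empty molecule set")
  hist <- atom_count_histogram(mols)
  cb <- mols[[1]]$codebook
  if (family == "marginal-simplex") {
    ac <- matrix(0, cb$n_a, cb$n_c)
    eq <- rep(0, cb$n_e)
    for (g in mols) {
      ai <- argmax_rows(g$A); ci <- argmax_rows(g$C)
      for (k in seq_len(g$N)) ac[ai[k], ci[k]] <- ac[ai[k], ci[k]] + 1
      if (nrow(g$E) > 0) eq <- eq + colSums(g$E)
    }
    ac <- ac / sum(ac)
    eq <- eq / sum(eq)
    a_spec <- categorical_prior_spec("marginal-simplex", blur_sigma,
                                     q = rowSums(ac))
    c_spec <- categorical_prior_spec("marginal-simplex", blur_sigma,
                                     q = colSums(ac))
    e_spec <- categorical_prior_spec("marginal-simplex", blur_sigma, q = eq)
    molecule_prior_spec(a_spec, c_spec, e_spec, hist, ac_joint = ac)
  } else {
    spec1 <- function() categorical_prior_spec(family, blur_sigma)
    molecule_prior_spec(spec1(), spec1(), spec1(), hist)
  }
}
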