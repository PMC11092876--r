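# Download-free synthetic fixtures: small valence-respecting molecules and
# toy categorical tasks. These stand in for curated datasets at desk scale:
# the molecules are chemically well-formed trees (optionally with one ring
# closure) over a small element set, with geometry relaxed under a simple
# harmonic objective — deliberately minimal realism, sufficient for
# exercising I/O, training, sampling and the quality metrics.

#' Fixture grammar
#'
#' @param elements named integer vector mapping heavy-element symbols to
#'   their fixed valence; hydrogens cap all remaining valence.
#' @param max_heavy maximum number of heavy atoms per molecule.
#' @param p_double probability that an eligible new attachment is a double
#'   bond.
#' @param p_ring probability of attempting one ring-closure move.
#' @return object of class `fixture_grammar`.
#' @export
fixture_grammar <- function(elements = c(C = 4L, N = 3L, O = 2L, F = 1L),
                            max_heavy = 6, p_double = 0.2, p_ring = 0) {
  if (max_heavy < 1) stop("max_heavy must be >= 1")
  structure(list(elements = elements, max_heavy = max_heavy,
                 p_double = p_double, p_ring = p_ring),
            class = "fixture_grammar")
}

#' Generate synthetic fixture molecules
#'
#' Random trees grown atom-by-atom respecting remaining valence: a first
#' heavy atom is drawn, further heavy atoms attach (by a single or sometimes
#' double bond) to atoms with spare valence, optionally one ring is closed,
#' and every remaining open valence is capped with hydrogen. Positions are
#' embedded by relaxing a harmonic bond-length/soft-repulsion objective from
#' a random start and centered at zero centroid. Every output satisfies its
#' declared valences exactly, so the set is 100% stable against its own
#' valency table and sanitizes cleanly.
#'
#' @param grammar a [fixture_grammar()].
#' @param count number of molecules.
#' @param codebook a [category_codebook()]; must contain "H", the grammar
#'   elements, charge 0 and the bond orders used.
#' @return list of one-hot, centered [molecule_graph()].
#' @export
generate_molecules <- function(grammar, count,
                               codebook = category_codebook()) {
  if (!"H" %in% codebook$elements) {
    stop("codebook must contain the valence-1 capper H")
  }
  missing <- setdiff(names(grammar$elements), codebook$elements)
  if (length(missing) > 0) {
    stop("grammar elements not in codebook: ", paste(missing, collapse = ", "))
  }
  lapply(seq_len(count), function(k) generate_one(grammar, codebook))
}

generate_one <- function(grammar, codebook) {
  els <- names(grammar$elements)
  n_heavy <- sample.int(grammar$max_heavy, 1)
  sym <- sample(els, 1, prob = grammar$elements)  # weight by valence
  atoms <- sym
  remaining <- unname(grammar$elements[sym])
  bonds <- data.frame(i = integer(0), j = integer(0), order = character(0),
                      stringsAsFactors = FALSE)
  add_bond <- function(i, j, order) {
    o <- bond_order_value(order)
    bonds <<- rbind(bonds, data.frame(i = i, j = j, order = order,
                                      stringsAsFactors = FALSE))
    remaining[i] <<- remaining[i] - o
    remaining[j] <<- remaining[j] - o
  }
  while (length(atoms) < n_heavy) {
    open <- which(remaining >= 1)
    if (length(open) == 0) break
    anchor <- if (length(open) == 1) open else sample(open, 1)
    sym <- sample(els, 1)
    atoms <- c(atoms, sym)
    remaining <- c(remaining, unname(grammar$elements[sym]))
    new <- length(atoms)
    dbl <- stats::runif(1) < grammar$p_double &&
      remaining[anchor] >= 2 && remaining[new] >= 2
    add_bond(anchor, new, if (dbl) "double" else "single")
  }
  if (grammar$p_ring > 0 && stats::runif(1) < grammar$p_ring) {
    open <- which(remaining >= 1)
    if (length(open) >= 2) {
      bonded <- paste(bonds$i, bonds$j)
      cand <- utils::combn(open, 2)
      free <- which(!(paste(cand[1, ], cand[2, ]) %in% bonded) &
                      cand[1, ] != cand[2, ])
      if (length(free) > 0) {
        pick <- cand[, if (length(free) == 1) free else sample(free, 1)]
        add_bond(pick[1], pick[2], "single")
      }
    }
  }
  # cap every open valence with hydrogen
  for (i in seq_along(remaining)) {
    while (remaining[i] >= 1) {
      atoms <- c(atoms, "H")
      remaining <- c(remaining, 1L)
      add_bond(i, length(atoms), "single")
    }
  }
  X <- embed_positions(length(atoms), bonds, atoms)
  center_molecule(encode_molecule(atoms, rep(0L, length(atoms)), bonds, X,
                                  codebook))
}

# relax a harmonic bond-length + soft-repulsion objective from random start
embed_positions <- function(n, bonds, atoms, iters = 300) {
  if (n == 1) return(matrix(0, 1, 3))
  X <- matrix(stats::rnorm(3 * n, sd = 2), n, 3)
  target <- ifelse(atoms[bonds$i] == "H" | atoms[bonds$j] == "H", 1.0, 1.5)
  bonded <- matrix(FALSE, n, n)
  bonded[cbind(bonds$i, bonds$j)] <- TRUE
  bonded <- bonded | t(bonded)
  obj <- function(x) {
    X <- matrix(x, n, 3)
    d <- as.matrix(stats::dist(X))
    e <- sum((d[cbind(bonds$i, bonds$j)] - target)^2)
    rep_pairs <- !bonded & upper.tri(d)
    e + sum(pmax(0, 1.8 - d[rep_pairs])^2)
  }
  gr <- function(x) {
    X <- matrix(x, n, 3)
    G <- matrix(0, n, 3)
    for (b in seq_len(nrow(bonds))) {
      i <- bonds$i[b]; j <- bonds$j[b]
      v <- X[i, ] - X[j, ]
      d <- sqrt(sum(v^2)) + 1e-12
      f <- 2 * (d - target[b]) * v / d
      G[i, ] <- G[i, ] + f
      G[j, ] <- G[j, ] - f
    }
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (bonded[i, j]) next
      v <- X[i, ] - X[j, ]
      d <- sqrt(sum(v^2)) + 1e-12
      if (d < 1.8) {
        f <- -2 * (1.8 - d) * v / d
        G[i, ] <- G[i, ] + f
        G[j, ] <- G[j, ] - f
      }
    }
    as.numeric(G)
  }
  fit <- stats::optim(as.numeric(X), obj, gr, method = "BFGS",
                      control = list(maxit = iters))
  center_positions(matrix(fit$par, n, 3))
}

#' Hand-built benzene fixture (aromatic ring + hydrogens)
#'
#' Six aromatic carbons on a regular hexagon with six hydrogens; used to
#' exercise the aromatic 1.5 bond-order arithmetic in the metrics.
#'
#' @param codebook a [category_codebook()] containing "aromatic".
#' @return a one-hot [molecule_graph()].
#' @export
benzene_fixture <- function(codebook = category_codebook()) {
  theta <- (0:5) * pi / 3
  rc <- 1.39; rh <- 2.47
  X <- rbind(cbind(rc * cos(theta), rc * sin(theta), 0),
             cbind(rh * cos(theta), rh * sin(theta), 0))
  ring <- data.frame(i = 1:6, j = c(2:6, 1), order = "aromatic",
                     stringsAsFactors = FALSE)
  ch <- data.frame(i = 1:6, j = 7:12, order = "single",
                   stringsAsFactors = FALSE)
  center_molecule(encode_molecule(rep(c("C", "H"), each = 6),
                                  rep(0L, 12), rbind(ring, ch), X, codebook))
}

#' One-hot samples for a toy categorical task
#'
#' Draws n one-hot rows with class probabilities q — the data side of the
#' desk-scale categorical-flow experiments.
#'
#' @param d number of categories.
#' @param q target distribution on the simplex.
#' @param n sample count.
#' @return n x d one-hot matrix; attribute `q` records the target.
#' @export
make_toy_task <- function(d, q, n) {
  if (length(q) != d || !assert_on_simplex(q, tol = 1e-8)) {
    stop("q must be a length-d vector on the simplex")
  }
  x <- to_onehot(sample.int(d, n, replace = TRUE, prob = q), d)
  attr(x, "q") <- q
  x
}
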