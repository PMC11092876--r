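# Molecule-quality evaluation: valency-based stability, sanitization
# validity, and Jensen-Shannon divergence of force-field energy
# distributions. Sanitization and MMFF94 energies come from RDKit through
# the bundled python helper (inst/python/chem_eval.py); stability is pure R.

#' Per-atom valences of a decoded molecule
#'
#' Valence of an atom is the sum of the orders of its incident bonds, with
#' aromatic bonds contributing 1.5.
#'
#' @param g a one-hot [molecule_graph()].
#' @return numeric vector of length N.
#' @export
atom_valences <- function(g) {
  val <- rep(0, g$N)
  dec <- decode_molecule(g)
  if (nrow(dec$bonds) > 0) {
    ords <- bond_order_value(dec$bonds$order)
    for (b in seq_len(nrow(dec$bonds))) {
      val[dec$bonds$i[b]] <- val[dec$bonds$i[b]] + ords[b]
      val[dec$bonds$j[b]] <- val[dec$bonds$j[b]] + ords[b]
    }
  }
  val
}

#' Build a valency table from a reference molecule set
#'
#' Records every (element, formal charge, valence) combination observed in
#' the reference set. An atom is later deemed stable iff its combination is
#' in the table, so by construction the reference set itself scores 100%.
#'
#' @param reference nonempty list of one-hot [molecule_graph()].
#' @return object of class `valency_table`: a named list mapping
#'   `"element/charge"` to the sorted set of observed valences.
#' @export
build_valency_table <- function(reference) {
  if (length(reference) == 0) stop("empty reference set")
  tab <- new.env(parent = emptyenv())
  for (g in reference) {
    dec <- decode_molecule(g)
    vals <- atom_valences(g)
    keys <- paste(dec$elements, dec$charges, sep = "/")
    for (i in seq_len(g$N)) {
      tab[[keys[i]]] <- union(tab[[keys[i]]], vals[i])
    }
  }
  out <- lapply(as.list(tab), sort)
  structure(out, class = "valency_table")
}

#' Atom and molecule stability of a molecule set
#'
#' An atom is stable if its (element, charge, valence) triple appears in the
#' valency table; a molecule is stable if all its atoms are. Atoms whose
#' element/charge pair was never seen in the reference are counted unstable.
#'
#' @param mols list of one-hot [molecule_graph()].
#' @param table a [build_valency_table()] result.
#' @param tol numeric tolerance when matching valences (aromatic arithmetic).
#' @return list: `atoms_stable_pct`, `mols_stable_pct`, `n_atoms`, `n_mols`.
#' @export
stability <- function(mols, table, tol = 1e-6) {
  n_atoms <- 0L; n_stable_atoms <- 0L; n_stable_mols <- 0L
  for (g in mols) {
    dec <- decode_molecule(g)
    vals <- atom_valences(g)
    keys <- paste(dec$elements, dec$charges, sep = "/")
    ok <- vapply(seq_len(g$N), function(i) {
      allowed <- table[[keys[i]]]
      !is.null(allowed) && any(abs(allowed - vals[i]) < tol)
    }, logical(1))
    n_atoms <- n_atoms + g$N
    n_stable_atoms <- n_stable_atoms + sum(ok)
    if (all(ok)) n_stable_mols <- n_stable_mols + 1L
  }
  list(atoms_stable_pct = 100 * n_stable_atoms / max(1L, n_atoms),
       mols_stable_pct = 100 * n_stable_mols / max(1L, length(mols)),
       n_atoms = n_atoms, n_mols = length(mols))
}

python_binary <- function() {
  Sys.which("python")
}

chem_eval_script <- function() {
  p <- system.file("python", "chem_eval.py", package = "molfm")
  if (!nzchar(p)) {
    # during development (devtools::load_all) fall back to the source tree
    p <- file.path("inst", "python", "chem_eval.py")
  }
  p
}

#' RDKit-backed evaluation of a molecule set
#'
#' Writes the molecules to a temporary SDF and runs the bundled RDKit
#' helper, returning per-molecule sanitization validity and (for valid
#' molecules with a computable force field) the MMFF94 potential energy.
#'
#' @param mols list of one-hot [molecule_graph()].
#' @return data.frame with columns `valid` (logical) and `energy` (numeric,
#'   NA where unavailable).
#' @export
rdkit_evaluate <- function(mols) {
  if (length(mols) == 0) {
    return(data.frame(valid = logical(0), energy = numeric(0)))
  }
  py <- python_binary()
  if (!nzchar(py)) stop("python not found on PATH; RDKit metrics unavailable")
  sdf <- tempfile(fileext = ".sdf")
  on.exit(unlink(sdf))
  write_sdf(mols, sdf)
  res <- system2(py, c(chem_eval_script(), sdf), stdout = TRUE, stderr = FALSE)
  parsed <- jsonlite::fromJSON(paste(res, collapse = ""),
                               simplifyVector = FALSE)
  data.frame(
    valid = vapply(parsed, function(r) isTRUE(r$valid), logical(1)),
    energy = vapply(parsed, function(r) {
      if (is.null(r$energy)) NA_real_ else as.numeric(r$energy)
    }, numeric(1)))
}

#' Percentage of molecules passing default sanitization
#'
#' @param mols list of one-hot [molecule_graph()].
#' @return list: `mols_valid_pct`, `n_mols`, `n_valid`. With `n_mols = 0`
#'   the percentage is reported as 0 and flagged.
#' @export
validity <- function(mols) {
  if (length(mols) == 0) {
    return(list(mols_valid_pct = 0, n_mols = 0L, n_valid = 0L, empty = TRUE))
  }
  ev <- rdkit_evaluate(mols)
  list(mols_valid_pct = 100 * mean(ev$valid), n_mols = length(mols),
       n_valid = sum(ev$valid), empty = FALSE)
}

#' Jensen-Shannon divergence between two discrete distributions
#'
#' `JS(p, q) = (KL(p||m) + KL(q||m)) / 2` with `m = (p + q) / 2`; symmetric
#' and bounded by log(2) nats (1 bit).
#'
#' @param p,q nonnegative vectors (normalized internally).
#' @param unit `"nats"` (natural log, default) or `"bits"` (log2).
#' @return a single nonnegative number.
#' @export
js_divergence <- function(p, q, unit = c("nats", "bits")) {
  unit <- match.arg(unit)
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log(a[i] / b[i]))
  }
  d <- (kl(p, m) + kl(q, m)) / 2
  if (unit == "bits") d / log(2) else d
}

shared_breaks <- function(x, min_bins = 20) {
  # Freedman-Diaconis on the pooled sample, floored at min_bins
  n <- length(x)
  iqr <- stats::IQR(x)
  h <- 2 * iqr / n^(1 / 3)
  nb <- if (h > 0) max(min_bins, ceiling(diff(range(x)) / h)) else min_bins
  if (diff(range(x)) == 0) {
    return(seq(x[1] - 0.5, x[1] + 0.5, length.out = nb + 1))
  }
  seq(min(x), max(x), length.out = nb + 1)
}

#' JS divergence of force-field energy distributions
#'
#' MMFF94 energies are computed for the sanitizable (valid) molecules of
#' each set; both energy samples are histogrammed on shared Freedman-
#' Diaconis bins over the pooled sample (minimum 20 bins) and the JS
#' divergence of the two histograms is returned.
#'
#' @param sample_mols,reference_mols lists of one-hot [molecule_graph()].
#' @param unit `"nats"` or `"bits"`.
#' @param min_bins lower bound on the number of shared bins.
#' @return list: `js`, `n_sample`, `n_reference` (valid molecules with an
#'   energy in each set).
#' @export
js_energy_divergence <- function(sample_mols, reference_mols, unit = "nats",
                                 min_bins = 20) {
  es <- rdkit_evaluate(sample_mols)
  er <- rdkit_evaluate(reference_mols)
  e1 <- es$energy[es$valid & !is.na(es$energy)]
  e2 <- er$energy[er$valid & !is.na(er$energy)]
  if (length(e1) == 0) stop("no valid molecules with energies in sample set")
  if (length(e2) == 0) stop("no valid molecules with energies in reference set")
  breaks <- shared_breaks(c(e1, e2), min_bins)
  h1 <- graphics::hist(pmin(pmax(e1, breaks[1]), breaks[length(breaks)]),
                       breaks = breaks, plot = FALSE)$counts
  h2 <- graphics::hist(pmin(pmax(e2, breaks[1]), breaks[length(breaks)]),
                       breaks = breaks, plot = FALSE)$counts
  list(js = js_divergence(h1, h2, unit), n_sample = length(e1),
       n_reference = length(e2))
}

#' Full evaluation report for a generated molecule set
#'
#' Combines stability, validity and (when energies are computable) the JS
#' energy divergence against a reference set, optionally over several
#' repeated samplings with normal-approximation 95% confidence intervals.
#'
#' @param sample_fn either a fixed list of molecules or a function(rep)
#'   returning a list of molecules for repeat `rep`.
#' @param reference list of one-hot reference molecules (also used to build
#'   the valency table).
#' @param repeats number of repeated samplings (default 1; the original
#'   evaluation protocol uses 5).
#' @param with_energy compute the JS energy divergence (requires RDKit).
#' @return data.frame with one row per metric: `mean`, `ci95` (NA when
#'   `repeats == 1`), `n`.
#' @export
eval_report <- function(sample_fn, reference, repeats = 1,
                        with_energy = TRUE) {
  table <- build_valency_table(reference)
  get_set <- if (is.function(sample_fn)) sample_fn else function(rep) sample_fn
  rows <- lapply(seq_len(repeats), function(rep) {
    mols <- get_set(rep)
    st <- stability(mols, table)
    va <- validity(mols)
    js <- if (with_energy) {
      tryCatch(js_energy_divergence(mols, reference)$js,
               error = function(e) NA_real_)
    } else NA_real_
    c(atoms_stable_pct = st$atoms_stable_pct,
      mols_stable_pct = st$mols_stable_pct,
      mols_valid_pct = va$mols_valid_pct, js_energy = js,
      n = length(mols))
  })
  m <- do.call(rbind, rows)
  ci <- function(x) {
    if (length(x) < 2 || all(is.na(x))) return(NA_real_)
    1.96 * stats::sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x)))
  }
  data.frame(metric = colnames(m)[1:4],
             mean = colMeans(m[, 1:4, drop = FALSE], na.rm = TRUE),
             ci95 = apply(m[, 1:4, drop = FALSE], 2, ci),
             n = sum(m[, "n"]), row.names = NULL)
}
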