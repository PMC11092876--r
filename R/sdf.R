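# SDF (MDL V2000) and XYZ I/O. No R cheminformatics toolkit ships with the
# target environment, so the small subset of V2000 needed here — 3D
# coordinates, elements, bond block with orders 1/2/3/4(aromatic), and
# "M  CHG" formal charges — is read and written directly. Files written by
# write_sdf() are plain V2000 readable by RDKit and friends.

sdf_bond_codes <- c(single = 1L, double = 2L, triple = 3L, aromatic = 4L)

#' Read molecules from an SDF file
#'
#' Parses a V2000 SDF with 3D coordinates and explicit hydrogens into
#' [molecule_graph()] objects. Every unordered atom pair not present in the
#' bond block receives a one-hot "none" bond row. Formal charges are taken
#' from `M  CHG` lines (the legacy charge column is ignored). Records whose
#' element, charge or bond order is not in the codebook are skipped with a
#' logged reason; a structurally unparsable file is a fatal error.
#'
#' @param path SDF file path.
#' @param codebook a [category_codebook()].
#' @return list of [molecule_graph()]; attributes `n_skipped` and
#'   `skip_reasons` report rejected records.
#' @export
read_sdf <- function(path, codebook = category_codebook()) {
  lines <- readLines(path, warn = FALSE)
  # split into records on $$$$
  recs <- list()
  start <- 1L
  for (k in seq_along(lines)) {
    if (trimws(lines[k]) == "$$$$") {
      recs[[length(recs) + 1L]] <- lines[start:(k - 1L)]
      start <- k + 1L
    }
  }
  if (start <= length(lines) && any(nzchar(trimws(lines[start:length(lines)])))) {
    recs[[length(recs) + 1L]] <- lines[start:length(lines)]
  }
  out <- list()
  skipped <- character(0)
  for (r in seq_along(recs)) {
    g <- tryCatch(parse_sdf_record(recs[[r]], codebook),
                  error = function(e) conditionMessage(e))
    if (is.character(g)) {
      skipped <- c(skipped, sprintf("record %d: %s", r, g))
      message("read_sdf: skipping record ", r, ": ", g)
    } else {
      out[[length(out) + 1L]] <- g
    }
  }
  attr(out, "n_skipped") <- length(skipped)
  attr(out, "skip_reasons") <- skipped
  out
}

parse_sdf_record <- function(rec, codebook) {
  if (length(rec) < 4) stop("truncated record")
  counts <- rec[4]
  if (nchar(counts) < 6) stop("malformed counts line")
  natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(natoms) || is.na(nbonds)) stop("malformed counts line")
  if (grepl("V3000", counts)) stop("V3000 records are not supported")
  if (length(rec) < 4 + natoms + nbonds) stop("truncated atom/bond block")
  atoms <- rec[4 + seq_len(natoms)]
  X <- matrix(0, natoms, 3)
  el <- character(natoms)
  for (i in seq_len(natoms)) {
    ln <- atoms[i]
    X[i, ] <- as.numeric(c(substr(ln, 1, 10), substr(ln, 11, 20),
                           substr(ln, 21, 30)))
    el[i] <- trimws(substr(ln, 31, 34))
  }
  if (any(is.na(X))) stop("malformed atom coordinates")
  bad <- setdiff(unique(el), codebook$elements)
  if (length(bad) > 0) stop("element not in codebook: ",
                            paste(bad, collapse = ", "))
  bonds <- if (nbonds > 0) rec[4 + natoms + seq_len(nbonds)] else character(0)
  bi <- bj <- integer(nbonds); bo <- character(nbonds)
  code_to_label <- names(sdf_bond_codes)
  for (b in seq_len(nbonds)) {
    ln <- bonds[b]
    bi[b] <- as.integer(substr(ln, 1, 3))
    bj[b] <- as.integer(substr(ln, 4, 6))
    code <- as.integer(substr(ln, 7, 9))
    if (is.na(code) || code < 1 || code > 4) {
      stop("unsupported bond type code: ", substr(ln, 7, 9))
    }
    bo[b] <- code_to_label[code]
  }
  bad <- setdiff(unique(bo), codebook$bond_orders)
  if (length(bad) > 0) stop("bond order not in codebook: ",
                            paste(bad, collapse = ", "))
  charges <- rep(0L, natoms)
  for (ln in rec[grepl("^M  CHG", rec)]) {
    nn <- as.integer(substr(ln, 7, 9))
    for (k in seq_len(nn)) {
      off <- 10 + (k - 1) * 8
      ai <- as.integer(substr(ln, off, off + 3))
      charges[ai] <- as.integer(substr(ln, off + 4, off + 7))
    }
  }
  bad <- setdiff(unique(charges), codebook$charges)
  if (length(bad) > 0) stop("charge not in codebook: ",
                            paste(bad, collapse = ", "))
  bonds_df <- if (nbonds > 0) {
    data.frame(i = bi, j = bj, order = bo, stringsAsFactors = FALSE)
  } else NULL
  encode_molecule(el, charges, bonds_df, X, codebook)
}

#' Write molecules to an SDF file
#'
#' Molecules are decoded by argmax (see [decode_molecule()]) before writing;
#' pairs with bond order "none" are omitted from the bond block. Nonzero
#' formal charges are written as `M  CHG` lines.
#'
#' @param mols list of [molecule_graph()] (or a single one).
#' @param path output file path.
#' @param names optional record names.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path, names = NULL) {
  if (inherits(mols, "molecule_graph")) mols <- list(mols)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(mols)) {
    dec <- decode_molecule(mols[[k]])
    nm <- if (!is.null(names)) names[k] else sprintf("mol_%d", k)
    writeLines(sdf_record_lines(dec, nm), con)
  }
  invisible(path)
}

sdf_record_lines <- function(dec, name) {
  n <- length(dec$elements)
  nb <- nrow(dec$bonds)
  lines <- c(name, "  molfm", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  for (i in seq_len(n)) {
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              dec$X[i, 1], dec$X[i, 2], dec$X[i, 3],
                              dec$elements[i]))
  }
  for (b in seq_len(nb)) {
    lines <- c(lines, sprintf("%3d%3d%3d  0", dec$bonds$i[b], dec$bonds$j[b],
                              sdf_bond_codes[[dec$bonds$order[b]]]))
  }
  chg <- which(dec$charges != 0)
  while (length(chg) > 0) {
    take <- utils::head(chg, 8)
    chg <- chg[-seq_along(take)]
    lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(take)),
                             paste0(sprintf("%4d%4d", take,
                                            dec$charges[take]),
                                    collapse = "")))
  }
  c(lines, "M  END", "$$$$")
}

#' Write positions to an XYZ file (debugging aid)
#' @param g a [molecule_graph()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(g, path) {
  dec <- decode_molecule(g)
  lines <- c(as.character(g$N), "molfm",
             sprintf("%s %.6f %.6f %.6f", dec$elements, g$X[, 1], g$X[, 2],
                     g$X[, 3]))
  writeLines(lines, path)
  invisible(path)
}
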