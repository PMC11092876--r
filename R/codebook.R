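#' Category codebook for molecular graphs
#'
#' Fixes the order of the categorical axes used throughout the package:
#' chemical elements (atom types), formal charge values, and bond orders.
#' One-hot axis order is semantic state, so the codebook is carried on every
#' molecule graph and serialized with every model checkpoint.
#'
#' @param elements character vector of element symbols, no duplicates.
#' @param charges integer vector of allowed formal charges, no duplicates.
#' @param bond_orders character vector of bond kind labels; must contain
#'   `"none"` (the explicit no-bond category of the fully connected graph).
#'
#' @return An object of class `category_codebook` with fields `elements`,
#'   `charges`, `bond_orders` and the derived counts `n_a`, `n_c`, `n_e`.
#' @examples
#' cb <- category_codebook()
#' cb$n_e  # 5 bond categories: none/single/double/triple/aromatic
#' @export
category_codebook <- function(elements = c("H", "C", "N", "O", "F"),
                              charges = c(-1L, 0L, 1L),
                              bond_orders = c("none", "single", "double",
                                              "triple", "aromatic")) {
  elements <- as.character(elements)
  charges <- as.integer(charges)
  bond_orders <- as.character(bond_orders)
  if (anyDuplicated(elements)) stop("duplicate element symbols in codebook")
  if (anyDuplicated(charges)) stop("duplicate charge values in codebook")
  if (anyDuplicated(bond_orders)) stop("duplicate bond order labels in codebook")
  if (!"none" %in% bond_orders) {
    stop("bond_orders must contain the explicit 'none' category")
  }
  structure(
    list(elements = elements, charges = charges, bond_orders = bond_orders,
         n_a = length(elements), n_c = length(charges),
         n_e = length(bond_orders)),
    class = "category_codebook")
}

#' @export
print.category_codebook <- function(x, ...) {
  cat("category_codebook\n")
  cat("  elements   :", paste(x$elements, collapse = " "), "\n")
  cat("  charges    :", paste(x$charges, collapse = " "), "\n")
  cat("  bond orders:", paste(x$bond_orders, collapse = " "), "\n")
  invisible(x)
}

# numeric bond order used for valency arithmetic; aromatic counts 1.5
bond_order_value <- function(labels) {
  vals <- c(none = 0, single = 1, double = 2, triple = 3, aromatic = 1.5)
  unknown <- setdiff(labels, names(vals))
  if (length(unknown) > 0) {
    stop("no numeric valence contribution defined for bond order(s): ",
         paste(unknown, collapse = ", "))
  }
  unname(vals[labels])
}

codebook_to_list <- function(cb) {
  list(elements = cb$elements, charges = cb$charges,
       bond_orders = cb$bond_orders)
}

codebook_from_list <- function(x) {
  category_codebook(elements = unlist(x$elements),
                    charges = unlist(x$charges),
                    bond_orders = unlist(x$bond_orders))
}
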