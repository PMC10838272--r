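#' Per-element bonding parameters
#'
#' Each element is described by two integers: `t`, the maximum total bond
#' order the neutral atom can carry (its remaining capacity is filled with
#' implicit hydrogens), and `b`, the maximum order of any single bond it can
#' form. Carbon is (4, 3) -- total order four but no quadruple bonds --
#' nitrogen (3, 3), and oxygen (2, 2): a neutral oxygen cannot exceed a double
#' bond without taking on formal charge, which is excluded throughout.
#'
#' @param symbols optional character vector to subset/order the table by.
#' @return a data.frame with columns `symbol`, `t`, `b`.
#' @examples
#' element_specs()
#' element_specs(c("O", "C"))
#' @export
element_specs <- function(symbols = NULL) {
  tab <- data.frame(
    symbol = c("C", "N", "O"),
    t = c(4L, 3L, 2L),
    b = c(3L, 3L, 2L),
    stringsAsFactors = FALSE
  )
  if (is.null(symbols)) return(tab)
  idx <- match(symbols, tab$symbol)
  if (anyNA(idx)) {
    stop("no bonding parameters for element(s): ",
         paste(unique(symbols[is.na(idx)]), collapse = ", "))
  }
  tab[idx, , drop = FALSE]
}

#' Ordered atom set with degeneracy classes
#'
#' An atom array is the fixed, ordered list of heavy atoms over which bond
#' matrices are built, together with a partition of the atom indices into
#' degeneracy classes: groups of chemically interchangeable atoms (for the
#' simple amine-acid system, the two carboxylic-acid oxygens, and the
#' unsubstituted carbons). Atoms in one class must share an element.
#'
#' @param symbols character vector of element symbols.
#' @param degeneracy_classes either `"by_element"` (all atoms of one element
#'   form a class), `"none"` (every atom its own class), or a list of integer
#'   index vectors partitioning `seq_along(symbols)`.
#' @param specs bonding-parameter table, see [element_specs()].
#' @return an object of class `atom_array`.
#' @examples
#' atom_array(c("C", "O"))
#' amine_acid_array()
#' @export
atom_array <- function(symbols, degeneracy_classes = "by_element",
                       specs = element_specs()) {
  stopifnot(is.character(symbols))
  sp <- element_specs(symbols)  # errors on unknown elements
  if (identical(degeneracy_classes, "by_element")) {
    degeneracy_classes <- unname(split(seq_along(symbols), symbols))
  } else if (identical(degeneracy_classes, "none")) {
    degeneracy_classes <- as.list(seq_along(symbols))
  } else {
    idx <- sort(unlist(degeneracy_classes))
    if (!identical(as.integer(idx), seq_along(symbols))) {
      stop("degeneracy_classes must partition the atom indices")
    }
    for (cl in degeneracy_classes) {
      if (length(unique(symbols[cl])) > 1L) {
        stop("atoms in one degeneracy class must share an element")
      }
    }
  }
  structure(
    list(symbols = symbols,
         t = sp$t, b = sp$b,
         degeneracy_classes = lapply(degeneracy_classes, as.integer)),
    class = "atom_array"
  )
}

#' The eight-atom amine-acid array
#'
#' The standard system underlying the enumeration: an ethylamine-like amine
#' fragment and a propanoic-acid-like acid fragment. Atom indexing is fixed:
#' 1 amine beta-carbon, 2 amine alpha-carbon, 3 acid beta-carbon, 4 acid
#' alpha-carbon, 5 carboxyl carbon, 6 nitrogen, 7 and 8 the acid oxygens.
#' All matrices, templates and transformation matrices in the package use this
#' convention; results are invariant to it by construction.
#'
#' @param carbon_degenerate if `TRUE` (default) the five carbons form one
#'   degeneracy class, as they do in the unsubstituted system; if `FALSE` only
#'   the two oxygens are degenerate.
#' @return an `atom_array` of 5 C, 1 N, 2 O.
#' @export
amine_acid_array <- function(carbon_degenerate = TRUE) {
  cls <- if (carbon_degenerate) {
    list(1:5, 6L, 7:8)
  } else {
    list(1L, 2L, 3L, 4L, 5L, 6L, 7:8)
  }
  atom_array(c("C", "C", "C", "C", "C", "N", "O", "O"),
             degeneracy_classes = cls)
}

#' @export
print.atom_array <- function(x, ...) {
  cat("<atom_array> ", paste(x$symbols, collapse = ""), "\n", sep = "")
  cat("  t: ", paste(x$t, collapse = " "), "   b: ",
      paste(x$b, collapse = " "), "\n", sep = "")
  cls <- vapply(x$degeneracy_classes,
                function(cl) paste(cl, collapse = ","), "")
  cat("  degeneracy classes: {", paste(cls, collapse = "} {"), "}\n", sep = "")
  invisible(x)
}

n_atoms <- function(atoms) length(atoms$symbols)

# integer class id per atom (1-based), from the class partition
class_ids <- function(atoms) {
  id <- integer(n_atoms(atoms))
  for (k in seq_along(atoms$degeneracy_classes)) {
    id[atoms$degeneracy_classes[[k]]] <- k
  }
  id
}
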