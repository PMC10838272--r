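#' Starting-material templates for the amine-acid system
#'
#' Four encodings of the unreacted amine + acid pair, one per combination of
#' amine and acid hybridization. On the standard eight-atom indexing (1 amine
#' beta-C, 2 amine alpha-C, 3 acid beta-C, 4 acid alpha-C, 5 carboxyl C, 6 N,
#' 7/8 O) every template carries the bonds 1-2, 2-6, 3-4, 4-5, 5=7 and 5-8;
#' the sp2 variant of a partner places a double bond between its alpha and
#' beta carbons (1=2 for the amine, 3=4 for the acid). The encoding of the
#' sp2 variants is a package convention (see the methods vignette) and can be
#' swapped by passing modified systems wherever templates are accepted.
#'
#' @param carbon_degenerate forwarded to [amine_acid_array()].
#' @return named list of four [mol_system()] objects: `sp3_sp3`, `sp3_sp2`,
#'   `sp2_sp3`, `sp2_sp2` (amine hybridization first).
#' @examples
#' sm_templates()$sp3_sp3$B[5, 7]  # the C=O double bond
#' @export
sm_templates <- function(carbon_degenerate = TRUE) {
  atoms <- amine_acid_array(carbon_degenerate)
  base <- matrix(0L, 8, 8)
  bond <- function(B, i, j, o) { B[i, j] <- B[j, i] <- as.integer(o); B }
  base <- bond(base, 1, 2, 1)
  base <- bond(base, 2, 6, 1)
  base <- bond(base, 3, 4, 1)
  base <- bond(base, 4, 5, 1)
  base <- bond(base, 5, 7, 2)
  base <- bond(base, 5, 8, 1)
  sp2_am <- bond(base, 1, 2, 2)
  sp2_ac <- bond(base, 3, 4, 2)
  sp2_both <- bond(sp2_am, 3, 4, 2)
  list(
    sp3_sp3 = mol_system(atoms, base),
    sp3_sp2 = mol_system(atoms, sp2_ac),
    sp2_sp3 = mol_system(atoms, sp2_am),
    sp2_sp2 = mol_system(atoms, sp2_both)
  )
}

#' Derive the transformation matrix of a reaction
#'
#' The transformation matrix is the elementwise difference between the product
#' bond matrix and the starting-material bond matrix: positive entries are
#' bonds formed, negative entries bonds broken. Adding it back to the starting
#' material reproduces the product exactly.
#'
#' @param product a [mol_system()] (or bond matrix).
#' @param sm the starting material, a [mol_system()] (or bond matrix) on the
#'   same atom array and ordering.
#' @return integer matrix of class `transformation_matrix`.
#' @examples
#' tm <- sm_templates()$sp3_sp3
#' amide <- apply_transformation(tm, amide_transformation())
#' derive_transformation(amide, tm)[5, 8]   # the broken C-OH bond
#' @export
derive_transformation <- function(product, sm) {
  Bp <- if (inherits(product, "mol_system")) product$B else product
  Bs <- if (inherits(sm, "mol_system")) sm$B else sm
  if (!all(dim(Bp) == dim(Bs))) {
    stop("product and starting material have different dimensions")
  }
  T <- Bp - Bs
  storage.mode(T) <- "integer"
  structure(T, class = c("transformation_matrix", class(T)))
}

#' The amide-coupling transformation matrix
#'
#' The classic condensation on the eight-atom system: the N6-C5 bond order
#' increases by one and the C5-O8 bond order decreases by one (water is lost
#' as the implicit hydrogens rearrange). Its bond edit distance is 2.
#'
#' @return integer 8 x 8 `transformation_matrix`.
#' @export
amide_transformation <- function() {
  T <- matrix(0L, 8, 8)
  T[6, 5] <- T[5, 6] <- 1L
  T[5, 8] <- T[8, 5] <- -1L
  structure(T, class = c("transformation_matrix", class(T)))
}

#' Bond edit distance of a transformation
#'
#' Half the sum of absolute values of the transformation-matrix entries (the
#' matrix is symmetric, so each unit bond-order change is counted once). Zero
#' if and only if the transformation is the identity.
#'
#' @param T a transformation matrix (symmetric integer matrix).
#' @return non-negative integer.
#' @examples
#' bond_edit_distance(amide_transformation())  # 2
#' @export
bond_edit_distance <- function(T) {
  stopifnot(is.matrix(T), nrow(T) == ncol(T))
  if (!isTRUE(all.equal(unclass(T), t(unclass(T)), check.attributes = FALSE))) {
    stop("transformation matrix must be symmetric")
  }
  tot <- sum(abs(T))
  stopifnot(tot %% 2 == 0)  # guaranteed by symmetry
  as.integer(tot / 2)
}

#' Apply a transformation matrix to a system
#'
#' Adds the transformation to the system's bond matrix and validates the
#' result; an invalid outcome (negative bond order, cap or octet violation) or
#' a sanitization failure is a rejection, not an error, so transformation
#' libraries can be applied in bulk.
#'
#' @param system a [mol_system()].
#' @param T transformation matrix of matching dimension.
#' @return the transformed [mol_system()], or `NULL` with attribute handling
#'   via [attr()]: on rejection returns an object of class `rxn_rejection`
#'   carrying the reason.
#' @examples
#' apply_transformation(sm_templates()$sp3_sp3, amide_transformation())
#' @export
apply_transformation <- function(system, T) {
  stopifnot(inherits(system, "mol_system"))
  if (!all(dim(T) == dim(system$B))) {
    return(rejection("dimension mismatch"))
  }
  B2 <- system$B + T
  chk <- validate_matrix(B2, system$atoms)
  if (!chk$valid) {
    return(rejection(paste(chk$violations, collapse = "; ")))
  }
  out <- mol_system(system$atoms, B2)
  if (is.na(system_to_smiles(out, canonical = TRUE))) {
    return(rejection("sanitization failure"))
  }
  out
}

rejection <- function(reason) {
  structure(list(reason = reason), class = "rxn_rejection")
}

#' @export
print.rxn_rejection <- function(x, ...) {
  cat("<rejected transformation>", x$reason, "\n")
  invisible(x)
}

#' Is a transformation result a rejection?
#' @param x result of [apply_transformation()].
#' @return logical.
#' @export
is_rejected <- function(x) inherits(x, "rxn_rejection")

#' Minimal bond edit distance of a product system over the template set
#'
#' For a full system on the standard eight-atom array, the minimum of
#' [bond_edit_distance()] of `B - template` across the four hybridization
#' templates, together with the template achieving it.
#'
#' @param product a [mol_system()] on the eight-atom array.
#' @param templates list of templates, default [sm_templates()].
#' @return list with `distance` (integer) and `template` (name of argmin).
#' @examples
#' min_edit_distance(sm_templates()$sp2_sp2)$distance  # 0
#' @export
min_edit_distance <- function(product, templates = sm_templates()) {
  d <- vapply(templates, function(sm) {
    bond_edit_distance(derive_transformation(product, sm))
  }, 1L)
  list(distance = min(d), template = names(templates)[which.min(d)])
}

#' Minimal bond edit distance of a product fragment
#'
#' A product here is a connected component (possibly fewer than eight atoms);
#' its distance is minimized over the four templates and over all injective
#' element-preserving placements of its atoms onto template positions. Bonds
#' between a placed and an unplaced template atom are always broken; the two
#' `residual` conventions differ in whether the unplaced template atoms keep
#' their mutual bonds (`"template"`, the true minimum over all systems
#' containing the product) or are fully fragmented (`"fragmented"`, the
#' product referenced against product-plus-bare-atoms; the convention that
#' reproduces the reference funnel count). See the methods vignette.
#'
#' @param system a [mol_system()] with at most 8 atoms, all C/N/O.
#' @param residual `"fragmented"` or `"template"`.
#' @param templates list of template systems, default [sm_templates()].
#' @return integer distance.
#' @examples
#' amide <- smiles_to_system("CCC(=O)NCC")
#' product_min_edit(amide)  # 2
#' @export
product_min_edit <- function(system, residual = c("fragmented", "template"),
                             templates = sm_templates()) {
  stopifnot(inherits(system, "mol_system"))
  residual <- match.arg(residual)
  sym <- system$atoms$symbols
  ord <- order(match(sym, c("C", "N", "O")))
  B <- system$B[ord, ord, drop = FALSE]
  counts <- c(sum(sym == "C"), sum(sym == "N"), sum(sym == "O"))
  if (sum(counts) != length(sym)) stop("product atoms must be C/N/O")
  if (counts[1] > 5 || counts[2] > 1 || counts[3] > 2) {
    stop("product does not fit the 8-atom template (at most 5 C, 1 N, 2 O)")
  }
  tmpl <- lapply(templates, function(s) unname(s$B))
  as.integer(min_edit_cpp(matrix(tri_of(B), nrow = 1), counts, tmpl,
                          residual == "fragmented"))
}
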