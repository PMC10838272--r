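#' Molecular system: atoms plus a symmetric bond-order matrix
#'
#' A `mol_system` couples an [atom_array()] with an n x n integer matrix `B`
#' whose (i, j) entry is the bond order between heavy atoms i and j. The
#' diagonal is zero, entries are capped by `min(b_i, b_j)`, and row sums never
#' exceed `t_i`; the slack `t_i - rowsum(i)` is the implicit hydrogen count of
#' atom i. One matrix may encode several molecules (disconnected fragments).
#'
#' @param atoms an [atom_array()].
#' @param B integer bond-order matrix, or a vector of row-major upper-triangle
#'   entries.
#' @return an object of class `mol_system`.
#' @examples
#' a <- atom_array(c("C", "O"))
#' mol_system(a, matrix(c(0, 2, 2, 0), 2))   # formaldehyde
#' @export
mol_system <- function(atoms, B) {
  stopifnot(inherits(atoms, "atom_array"))
  n <- n_atoms(atoms)
  if (!is.matrix(B)) B <- tri_to_full(as.integer(B), n)
  storage.mode(B) <- "integer"
  chk <- validate_matrix(B, atoms)
  if (!chk$valid) {
    stop("invalid bond matrix: ", paste(chk$violations, collapse = "; "))
  }
  dimnames(B) <- list(atoms$symbols, atoms$symbols)
  structure(list(atoms = atoms, B = B), class = "mol_system")
}

#' @export
print.mol_system <- function(x, ...) {
  cat("<mol_system> ", paste(x$atoms$symbols, collapse = ""),
      ", ", sum(x$B[upper.tri(x$B)] > 0), " bond(s)\n", sep = "")
  print(x$B)
  cat("SMILES:", system_to_smiles(x), "\n")
  invisible(x)
}

#' Validate a bond-order matrix against an atom array
#'
#' Checks every structural invariant: square symmetric integer matrix, zero
#' diagonal, non-negative entries, per-pair caps `min(b_i, b_j)` (an atom
#' cannot exceed its maximum single-bond order), and per-row octet caps
#' `rowsum(i) <= t_i` so that no neutral atom exceeds its total bond order.
#'
#' @param B matrix to check.
#' @param atoms an [atom_array()].
#' @return list with `valid` (logical) and `violations` (character vector
#'   naming each offending entry or row).
#' @examples
#' a <- atom_array(c("C", "C"))
#' validate_matrix(matrix(c(0, 5, 5, 0), 2), a)$violations
#' @export
validate_matrix <- function(B, atoms) {
  stopifnot(inherits(atoms, "atom_array"))
  v <- character(0)
  n <- n_atoms(atoms)
  if (!is.matrix(B) || nrow(B) != ncol(B)) {
    return(list(valid = FALSE, violations = "matrix is not square"))
  }
  if (nrow(B) != n) {
    return(list(valid = FALSE,
                violations = sprintf("matrix is %d x %d but atom array has %d atoms",
                                     nrow(B), ncol(B), n)))
  }
  if (any(B != round(B))) {
    return(list(valid = FALSE, violations = "non-integer entries"))
  }
  if (!isTRUE(all.equal(B, t(B), check.attributes = FALSE))) {
    v <- c(v, "matrix is not symmetric")
  }
  if (any(diag(B) != 0)) v <- c(v, "nonzero diagonal")
  neg <- which(B < 0, arr.ind = TRUE)
  for (r in seq_len(nrow(neg))) {
    if (neg[r, 1] < neg[r, 2])
      v <- c(v, sprintf("negative bond order at (%d,%d)", neg[r, 1], neg[r, 2]))
  }
  cap <- outer(atoms$b, atoms$b, pmin)
  over <- which(B > cap & upper.tri(B), arr.ind = TRUE)
  for (r in seq_len(nrow(over))) {
    i <- over[r, 1]; j <- over[r, 2]
    v <- c(v, sprintf("bond order %d at (%d,%d) exceeds cap %d",
                      B[i, j], i, j, cap[i, j]))
  }
  rs <- rowSums(pmax(B, 0)) - pmax(diag(B), 0)
  bad <- which(rs > atoms$t)
  for (i in bad) {
    v <- c(v, sprintf("octet violation row %d: total order %d > t = %d",
                      i, rs[i], atoms$t[i]))
  }
  list(valid = length(v) == 0L, violations = v)
}

# row-major upper triangle <-> full symmetric matrix
tri_to_full <- function(tri, n) {
  B <- matrix(0L, n, n)
  if (n >= 2) {
    k <- 1L
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        B[i, j] <- B[j, i] <- tri[k]
        k <- k + 1L
      }
    }
  }
  B
}

tri_of <- function(B) {
  n <- nrow(B)
  if (n < 2) return(integer(0))
  out <- integer(n * (n - 1L) / 2L)
  k <- 1L
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      out[k] <- B[i, j]
      k <- k + 1L
    }
  }
  out
}

#' Implicit hydrogen counts of a system
#'
#' @param system a [mol_system()].
#' @return integer vector, `t_i - rowsum(i)` per atom.
#' @export
implicit_hydrogens <- function(system) {
  stopifnot(inherits(system, "mol_system"))
  as.integer(system$atoms$t - rowSums(system$B))
}

#' Connected components of a system
#'
#' @param system a [mol_system()].
#' @return integer vector of component labels, one per atom.
#' @export
system_components <- function(system) {
  comp_labels(system$B)
}

comp_labels <- function(B) {
  n <- nrow(B)
  lab <- rep(NA_integer_, n)
  nc <- 0L
  for (s in seq_len(n)) {
    if (!is.na(lab[s])) next
    nc <- nc + 1L
    stack <- s
    lab[s] <- nc
    while (length(stack)) {
      u <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      nb <- which(B[u, ] > 0 & is.na(lab))
      lab[nb] <- nc
      stack <- c(stack, nb)
    }
  }
  lab
}

#' Encode a molecule (SMILES) as a molecular system
#'
#' Heavy atoms are indexed in order of appearance in the SMILES string unless
#' `atom_order` reassigns them; aromatic rings are kekulized so every entry is
#' an integer bond order. Charged atoms and elements without bonding
#' parameters are rejected: the encoding covers neutral C/H/N/O chemistry
#' only.
#'
#' @param smiles a single SMILES string.
#' @param atom_order optional integer permutation: `atom_order[k]` is the index
#'   in the output matrix of the k-th atom of the parsed molecule.
#' @param carbon_degenerate passed to the degeneracy classes of the resulting
#'   atom array (by-element classes are used).
#' @return a [mol_system()].
#' @examples
#' s <- smiles_to_system("CCN.CCC(=O)O",
#'                       atom_order = c(1, 2, 6, 3, 4, 5, 7, 8))
#' s$B[2, 6]   # the alpha-carbon--nitrogen single bond
#' @export
smiles_to_system <- function(smiles, atom_order = NULL) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  g <- mol_graph(smiles)
  if (any(g$charge != 0)) {
    stop("charged atoms are not representable (atom ",
         paste(which(g$charge != 0), collapse = ","),
         "); only neutral systems are supported")
  }
  element_specs(g$symbols)  # errors for unsupported elements
  n <- g$n
  if (is.null(atom_order)) atom_order <- seq_len(n)
  stopifnot(length(atom_order) == n, !anyDuplicated(atom_order))
  B <- matrix(0L, n, n)
  B[atom_order, atom_order] <- g$B
  mol_system(atom_array(g$symbols[order(atom_order)]), B)
}

#' Decode a molecular system into SMILES
#'
#' The inverse of [smiles_to_system()]: atoms are emitted with implicit
#' hydrogens filling their remaining total bond order, fragments are joined
#' with `.`. With `canonical = TRUE` the string is canonicalized (and aromatic
#' rings re-perceived) by OpenBabel; a canonicalization failure returns `NA`
#' rather than an error so that batch pipelines can flag and skip the record.
#'
#' @param system a [mol_system()] (or a list of them).
#' @param canonical return canonical SMILES instead of the raw traversal.
#' @return character vector of SMILES.
#' @examples
#' a <- atom_array(c("C", "N", "O"))
#' system_to_smiles(mol_system(a, matrix(0L, 3, 3)))  # "C.N.O"
#' @export
system_to_smiles <- function(system, canonical = FALSE) {
  if (inherits(system, "mol_system")) system <- list(system)
  smi <- vapply(system, function(s) {
    tri_to_smiles_cpp(matrix(tri_of(s$B), nrow = 1), s$atoms$symbols)
  }, "")
  if (canonical) canonical_smiles(smi) else smi
}

#' Canonical SMILES via OpenBabel
#'
#' Canonicalization is run twice (output fed back through the canonicalizer):
#' for a few borderline ring systems OpenBabel's aromaticity perception
#' depends on the input atom order, and the second pass converges the two
#' possible spellings onto one fixed point, which the deduplication stages
#' rely on.
#'
#' @param smiles character vector.
#' @return character vector of canonical SMILES, `NA` where the input could
#'   not be parsed or sanitized.
#' @export
canonical_smiles <- function(smiles) {
  out <- canonical_pass(smiles)
  ok <- !is.na(out)
  if (any(ok)) out[ok] <- canonical_pass(out[ok])
  out
}

canonical_pass <- function(smiles) {
  n <- length(smiles)
  if (n == 0L) return(character(0))
  fin <- tempfile(fileext = ".smi")
  fout <- tempfile(fileext = ".smi")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(paste(smiles, seq_len(n)), fin)
  run_obabel(c(fin, "-ocan", "-e", "-O", fout))
  out <- rep(NA_character_, n)
  if (file.exists(fout)) {
    lines <- readLines(fout, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "[ \t]+")
    for (p in parts) {
      if (length(p) >= 2) {
        idx <- suppressWarnings(as.integer(p[[2]]))
        if (!is.na(idx)) out[idx] <- p[[1]]
      }
    }
  }
  out
}

run_obabel <- function(args) {
  res <- suppressWarnings(
    system2("obabel", args, stdout = TRUE, stderr = FALSE)
  )
  invisible(res)
}

#' Canonicalize a matrix under its degeneracy group
#'
#' Returns the lexicographically minimal matrix (by row-major upper triangle)
#' over all permutations of atoms within degeneracy classes. Two matrices get
#' the same key if and only if they are related by such a permutation, so the
#' key is a dedup handle for degenerate-atom symmetry.
#'
#' @param system a [mol_system()], or a bond matrix with `atoms` supplied.
#' @param atoms an [atom_array()] (ignored when `system` is a `mol_system`).
#' @return the canonical bond matrix (integer, same dimensions).
#' @export
canonical_under_group <- function(system, atoms = NULL) {
  if (inherits(system, "mol_system")) {
    atoms <- system$atoms
    B <- system$B
  } else {
    B <- system
    stopifnot(inherits(atoms, "atom_array"))
  }
  perms <- degeneracy_perms(atoms)
  best <- tri_of(B)
  bestB <- B
  for (p in perms) {
    Bp <- B[p, p, drop = FALSE]
    trip <- tri_of(Bp)
    cmp <- compare_tri(trip, best)
    if (cmp < 0) {
      best <- trip
      bestB <- Bp
    }
  }
  dimnames(bestB) <- dimnames(B)
  bestB
}

# all atom permutations that only move atoms within a degeneracy class
degeneracy_perms <- function(atoms) {
  n <- n_atoms(atoms)
  per_class <- lapply(atoms$degeneracy_classes, function(cl) {
    if (length(cl) == 1L) return(list(cl))
    apply(perm_matrix(length(cl)), 1, function(o) cl[o], simplify = FALSE)
  })
  grids <- expand.grid(lapply(per_class, seq_along))
  out <- vector("list", nrow(grids))
  for (r in seq_len(nrow(grids))) {
    p <- integer(n)
    for (k in seq_along(per_class)) {
      p[atoms$degeneracy_classes[[k]]] <- per_class[[k]][[grids[r, k]]]
    }
    out[[r]] <- p
  }
  out
}

# all permutations of 1..m as rows
perm_matrix <- function(m) {
  if (m == 1L) return(matrix(1L, 1, 1))
  sub <- perm_matrix(m - 1L)
  out <- NULL
  for (k in seq_len(m)) {
    ins <- cbind(sub[, seq_len(k - 1), drop = FALSE], m,
                 sub[, seq_len(m - 1) >= k, drop = FALSE])
    out <- rbind(out, ins)
  }
  unname(out)
}

compare_tri <- function(a, b) {
  d <- a - b
  nz <- which(d != 0)
  if (!length(nz)) return(0L)
  if (d[nz[1]] < 0) -1L else 1L
}
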