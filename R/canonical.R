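#' Count orbits of the enumeration under a degeneracy group
#'
#' The number of distinct matrices once atoms within degeneracy classes are
#' treated as interchangeable, computed with Burnside's lemma: the orbit count
#' is the mean, over the group elements, of the number of matrices each
#' element fixes. Fixed-matrix counts come from a constrained enumeration that
#' ties matrix entries along the pair-orbits of the permutation, so no matrix
#' is ever materialized. `method = "direct"` instead counts lexicographically
#' minimal representatives by full enumeration -- an independent route that
#' must agree with Burnside exactly.
#'
#' @param atoms an [atom_array()]; its degeneracy classes define the group.
#' @param method `"burnside"` (default, fast) or `"direct"`.
#' @return numeric orbit count.
#' @examples
#' a <- atom_array(c("C", "O", "O"))
#' count_orbit_matrices(a) == count_orbit_matrices(a, method = "direct")
#' @export
count_orbit_matrices <- function(atoms, method = c("burnside", "direct")) {
  stopifnot(inherits(atoms, "atom_array"))
  method <- match.arg(method)
  if (method == "direct") {
    return(count_orbits_direct_cpp(atoms$t, atoms$b, class_ids(atoms)))
  }
  perms <- degeneracy_perms(atoms)
  total <- 0
  for (p in perms) {
    if (all(p == seq_along(p))) {
      total <- total + count_matrices_cpp(atoms$t, atoms$b, -1L)$count
    } else {
      total <- total + count_fixed_cpp(atoms$t, atoms$b, as.integer(p - 1L))
    }
  }
  total / length(perms)
}

#' Deduplicate enumerated systems into unique products
#'
#' Converts each bond matrix to its molecule(s), splits multi-molecule systems
#' into connected components, keeps components with at least `min_heavy_atoms`
#' heavy atoms, and deduplicates by canonical SMILES -- which collapses both
#' oxygen and unsubstituted-carbon degeneracy, since isomorphic graphs share a
#' canonical string. Each unique product keeps the first-encountered witness
#' matrix (stream order breaks ties).
#'
#' @param systems list of [mol_system()] objects (e.g. from
#'   [enumerate_matrices()]).
#' @param min_heavy_atoms minimum component size kept, default 4.
#' @return data.frame with columns `smiles`, `n_heavy_atoms`, and a
#'   `witness` list column holding one bond matrix per product; sanitization
#'   failures are dropped and reported via the `n_failed` attribute.
#' @export
unique_products <- function(systems, min_heavy_atoms = 4) {
  if (inherits(systems, "mol_system")) systems <- list(systems)
  frag_smi <- character(0)
  frag_n <- integer(0)
  frag_witness <- list()
  for (s in systems) {
    lab <- comp_labels(s$B)
    sizes <- table(lab)
    for (cmp in names(sizes)) {
      if (sizes[[cmp]] < min_heavy_atoms) next
      idx <- which(lab == as.integer(cmp))
      sub <- s$B[idx, idx, drop = FALSE]
      frag_smi <- c(frag_smi,
                    tri_to_smiles_cpp(matrix(tri_of(sub), nrow = 1),
                                      s$atoms$symbols[idx]))
      frag_n <- c(frag_n, length(idx))
      frag_witness[[length(frag_witness) + 1L]] <- s$B
    }
  }
  if (!length(frag_smi)) {
    out <- data.frame(smiles = character(0), n_heavy_atoms = integer(0))
    out$witness <- list()
    attr(out, "n_failed") <- 0L
    return(out)
  }
  can <- canonical_smiles(frag_smi)
  failed <- is.na(can)
  keep <- which(!failed & !duplicated(can))
  out <- data.frame(smiles = can[keep], n_heavy_atoms = frag_n[keep],
                    stringsAsFactors = FALSE)
  out$witness <- frag_witness[keep]
  attr(out, "n_failed") <- sum(failed)
  out
}

#' Full census of unique amine-acid products
#'
#' The workhorse behind the enumeration funnel: for every sub-multiset of the
#' atom array with at least `min_heavy_atoms` atoms, all connected
#' valence-legal graphs are enumerated up to atom-permutation symmetry
#' (lexicographically minimal representatives under the full
#' identical-element group), converted to SMILES, canonicalized, and
#' deduplicated; canonicalization merges the kekulized resonance forms of
#' aromatic rings. Each unique product carries its heavy-atom count, its
#' cyclomatic ring count and its minimal bond edit distance to the
#' starting-material templates (see [product_min_edit()] for the two residual
#' conventions).
#'
#' @param atoms the full atom array, default [amine_acid_array()].
#' @param min_heavy_atoms smallest product kept, default 4.
#' @param residual `"fragmented"` (default) or `"template"`, the convention
#'   for template atoms not covered by the product; see the methods vignette.
#' @param templates list of starting-material systems, default
#'   [sm_templates()].
#' @return data.frame with columns `smiles`, `n_heavy_atoms`,
#'   `min_bond_edit_distance`, `rings`.
#' @export
product_census <- function(atoms = amine_acid_array(), min_heavy_atoms = 4,
                           residual = c("fragmented", "template"),
                           templates = sm_templates()) {
  stopifnot(inherits(atoms, "atom_array"))
  residual <- match.arg(residual)
  counts <- table(factor(atoms$symbols, levels = c("C", "N", "O")))
  if (any(is.na(match(atoms$symbols, c("C", "N", "O"))))) {
    stop("product census supports C/N/O atom arrays")
  }
  tmpl <- lapply(templates, function(s) unname(s$B))
  smi <- character(0)
  nat <- integer(0)
  dist <- integer(0)
  rng <- integer(0)
  for (nc in 0:counts[["C"]]) for (nn in 0:counts[["N"]]) for (no in 0:counts[["O"]]) {
    k <- nc + nn + no
    if (k < min_heavy_atoms) next
    sym <- c(rep("C", nc), rep("N", nn), rep("O", no))
    sub <- atom_array(sym)
    tri <- unique_connected_cpp(sub$t, sub$b, class_ids(sub))
    if (nrow(tri) == 0L) next
    smi <- c(smi, tri_to_smiles_cpp(tri, sym))
    nat <- c(nat, rep(k, nrow(tri)))
    dist <- c(dist, min_edit_cpp(tri, c(nc, nn, no), tmpl,
                                 residual == "fragmented"))
    edges <- rowSums(tri >= 1L)
    rng <- c(rng, as.integer(edges - k + 1L))  # connected components
  }
  can <- canonical_smiles(smi)
  ok <- !is.na(can)
  df <- data.frame(smiles = can[ok], n_heavy_atoms = nat[ok],
                   min_bond_edit_distance = dist[ok], rings = rng[ok],
                   stringsAsFactors = FALSE)
  # resonance forms merged: distance is the minimum over merged records
  agg <- stats::aggregate(
    cbind(n_heavy_atoms, min_bond_edit_distance, rings) ~ smiles, df, min)
  agg[order(agg$min_bond_edit_distance, agg$smiles), , drop = FALSE]
}
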