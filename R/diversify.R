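#' Map the eight template positions onto a substrate pair
#'
#' Locates the primary amine (N plus alpha and beta carbons) and the
#' carboxylic acid (carboxyl carbon, both oxygens, alpha and beta carbons) in
#' a substrate pair and returns the atom indices, in template order, at which
#' transformations will be applied. The substrate pair is encoded as one
#' system (amine SMILES first, then acid; indices of the acid are offset by
#' the amine's atom count). Hybridization must match the template: the
#' alpha-beta carbon bond must be single for an sp3 partner and double for an
#' sp2 partner.
#'
#' When several chemically distinct matches exist, all are reported in the
#' `matches` attribute, the first in canonical atom order is used, and a
#' warning is raised. No match is an error ("pattern not found").
#'
#' @param amine,acid SMILES strings.
#' @param template name (`"sp3_sp3"`, `"sp3_sp2"`, `"sp2_sp3"`, `"sp2_sp2"`)
#'   or a template from [sm_templates()].
#' @return integer vector of length 8: combined-system atom index for each
#'   template position (1 amine beta-C, 2 amine alpha-C, 3 acid beta-C,
#'   4 acid alpha-C, 5 carboxyl C, 6 N, 7/8 O). The combined `mol_graph` is
#'   attached as attribute `graph`.
#' @export
map_template_atoms <- function(amine, acid, template = "sp3_sp3") {
  tname <- if (is.character(template)) template else template_name_of(template)
  am_sp2 <- startsWith(tname, "sp2")
  ac_sp2 <- endsWith(tname, "sp2")
  ga <- mol_graph(amine)
  gc <- mol_graph(acid)
  g <- merge_graphs(ga, gc)
  off <- ga$n

  amine_hits <- find_primary_amine(ga, sp2 = am_sp2)
  acid_hits <- find_carboxylic_acid(gc, sp2 = ac_sp2)
  if (!length(amine_hits)) {
    stop("pattern not found: no matching primary amine (",
         if (am_sp2) "sp2" else "sp3", " alpha-beta) in the amine substrate")
  }
  if (!length(acid_hits)) {
    stop("pattern not found: no matching carboxylic acid (",
         if (ac_sp2) "sp2" else "sp3", " alpha-beta) in the acid substrate")
  }
  all_maps <- list()
  for (ah in amine_hits) for (ch in acid_hits) {
    all_maps[[length(all_maps) + 1L]] <- c(
      ah["beta"], ah["alpha"],                   # 1, 2
      off + ch["beta"], off + ch["alpha"],       # 3, 4
      off + ch["carboxyl"], ah["N"],             # 5, 6
      off + ch["O1"], off + ch["O2"]             # 7, 8
    )
  }
  if (length(all_maps) > 1L) {
    warning(length(all_maps), " distinct template matches; using the first ",
            "in canonical atom order")
  }
  out <- as.integer(all_maps[[1]])
  names(out) <- c("am_beta", "am_alpha", "ac_beta", "ac_alpha",
                  "carboxyl", "N", "O1", "O2")
  attr(out, "matches") <- all_maps
  attr(out, "graph") <- g
  out
}

template_name_of <- function(template) {
  tm <- sm_templates()
  for (nm in names(tm)) {
    if (isTRUE(all.equal(unname(tm[[nm]]$B), unname(template$B)))) return(nm)
  }
  stop("unrecognized template system")
}

merge_graphs <- function(g1, g2) {
  n <- g1$n + g2$n
  B <- matrix(0L, n, n)
  B[seq_len(g1$n), seq_len(g1$n)] <- g1$B
  B[g1$n + seq_len(g2$n), g1$n + seq_len(g2$n)] <- g2$B
  arom <- matrix(FALSE, n, n)
  arom[seq_len(g1$n), seq_len(g1$n)] <- g1$aromatic_edges
  arom[g1$n + seq_len(g2$n), g1$n + seq_len(g2$n)] <- g2$aromatic_edges
  rings <- c(g1$rings, lapply(g2$rings, function(r) r + g1$n))
  list(n = n, symbols = c(g1$symbols, g2$symbols), B = B,
       charge = c(g1$charge, g2$charge), aromatic_edges = arom, rings = rings)
}

# primary amine: neutral N with exactly one heavy neighbor (the alpha carbon),
# which must have a beta carbon with the requested alpha-beta bond order
find_primary_amine <- function(g, sp2 = FALSE) {
  want <- if (sp2) 2L else 1L
  hits <- list()
  for (N in which(g$symbols == "N" & g$charge == 0)) {
    nb <- which(g$B[N, ] > 0)
    if (length(nb) != 1L || g$symbols[nb] != "C" || g$B[N, nb] != 1L) next
    alpha <- nb
    if (!sp2 && any(g$B[alpha, ] >= 2L)) next  # sp3 template needs an sp3 alpha
    for (beta in which(g$B[alpha, ] == want & g$symbols == "C")) {
      if (beta == N) next
      hits[[length(hits) + 1L]] <- c(N = N, alpha = alpha, beta = beta)
    }
  }
  hits
}

# carboxylic acid: C(=O)(OH) carbon with an alpha carbon carrying a beta
# carbon of the requested alpha-beta bond order; O1 is the carbonyl oxygen
find_carboxylic_acid <- function(g, sp2 = FALSE) {
  want <- if (sp2) 2L else 1L
  hits <- list()
  for (cx in which(g$symbols == "C")) {
    os <- which(g$symbols == "O" & g$B[cx, ] > 0 & g$charge == 0)
    if (length(os) != 2L) next
    dbl <- os[g$B[cx, os] == 2L]
    sgl <- os[g$B[cx, os] == 1L]
    if (length(dbl) != 1L || length(sgl) != 1L) next
    if (sum(g$B[sgl, ] > 0) != 1L) next  # the OH oxygen has no other bond
    alphas <- which(g$symbols == "C" & g$B[cx, ] == 1L)
    for (alpha in alphas) {
      if (!sp2 && any(g$B[alpha, ] >= 2L)) next
      for (beta in which(g$B[alpha, ] == want & g$symbols == "C")) {
        if (beta == cx) next
        hits[[length(hits) + 1L]] <- c(carboxyl = cx, alpha = alpha,
                                       beta = beta, O1 = dbl, O2 = sgl)
      }
    }
  }
  hits
}

#' Late-stage diversification of a substrate pair
#'
#' Applies every transformation matrix in a library to the mapped reaction
#' center of a substituted amine-acid pair. Bond-order edits touch only
#' mapped-atom pairs; products violating the octet rule (which happens
#' naturally when a substituted alpha or beta carbon has less spare valence
#' than the unsubstituted template assumed), producing negative bond orders,
#' or failing sanitization are rejected and counted per category. Optional
#' predicates mirror the filters used for drug-like substrates: strained-motif
#' removal, substrate aromaticity retention, "lost significant substituent"
#' removal (any unmapped heavy atom separated from the main product), and
#' ring retention at the reacting atoms.
#'
#' @param amine,acid SMILES strings.
#' @param library list of 8 x 8 transformation matrices, or a 3-d array, or a
#'   matrix of upper-triangle rows.
#' @param template template name or system, as in [map_template_atoms()].
#' @param remove_strained drop products matching [strained_motif_patterns()].
#' @param keep_aromatic drop products that break substrate aromatic rings.
#' @param no_substituent_loss drop products where an unmapped heavy atom ends
#'   up outside the component holding the majority of the substrate.
#' @param retain_ring_size if non-`NULL`, require a ring of this size through
#'   the mapped atoms that had one in the substrates.
#' @return data.frame with columns `index`, `smiles`, `status` (`"ok"` or the
#'   rejection category); attribute `mapping` carries the atom mapping.
#'   Accepted plus per-category rejected counts always partition the library.
#' @export
diversify <- function(amine, acid, library, template = "sp3_sp3",
                      remove_strained = FALSE, keep_aromatic = FALSE,
                      no_substituent_loss = FALSE, retain_ring_size = NULL) {
  mapping <- map_template_atoms(amine, acid, template)
  g <- attr(mapping, "graph")
  lib <- as_transformation_list(library)
  n <- g$n
  mapped <- as.integer(mapping)
  caps <- element_specs(g$symbols[mapped])

  res_smiles <- rep(NA_character_, length(lib))
  status <- rep(NA_character_, length(lib))
  raw <- vector("list", length(lib))

  for (k in seq_along(lib)) {
    T <- lib[[k]]
    B2 <- g$B
    B2[mapped, mapped] <- B2[mapped, mapped] + T
    sub <- B2[mapped, mapped]
    if (any(sub < 0)) { status[k] <- "negative_bond"; next }
    capm <- outer(caps$b, caps$b, pmin)
    if (any(sub > capm)) { status[k] <- "bond_cap"; next }
    if (any(rowSums(B2[mapped, , drop = FALSE]) > caps$t)) {
      status[k] <- "octet"
      next
    }
    smi <- tri_to_smiles_cpp(matrix(tri_of(B2), nrow = 1), g$symbols)
    raw[[k]] <- B2
    res_smiles[k] <- smi
    status[k] <- "ok"
  }

  # sanitization pass in one batch
  ok <- which(status == "ok")
  if (length(ok)) {
    can <- canonical_smiles(res_smiles[ok])
    bad <- is.na(can)
    status[ok[bad]] <- "sanitization"
    res_smiles[ok] <- ifelse(bad, res_smiles[ok], can)
    ok <- ok[!bad]
  }

  if (no_substituent_loss && length(ok)) {
    # a substituent is lost when an unmapped heavy atom ends up in a
    # component retaining fewer than two reaction-center atoms: the
    # decoration rides away on a single severed center atom (or is fully
    # detached), instead of staying with a coherent piece of the core
    unmapped <- setdiff(seq_len(n), mapped)
    lost <- vapply(ok, function(k) {
      if (!length(unmapped)) return(FALSE)
      lab <- comp_labels(raw[[k]])
      mapped_per_comp <- table(factor(lab[mapped], levels = unique(lab)))
      any(mapped_per_comp[as.character(lab[unmapped])] < 2)
    }, TRUE)
    status[ok[lost]] <- "substituent_loss"
    ok <- ok[!lost]
  }

  if (keep_aromatic && length(ok)) {
    broke <- vapply(ok, function(k) {
      gp <- list(n = n, symbols = g$symbols, B = raw[[k]],
                 charge = g$charge)
      gp$rings <- graph_rings(gp$B)
      gp$aromatic_edges <- perceive_aromatic(gp)
      !aromaticity_preserved(g, gp)
    }, TRUE)
    status[ok[broke]] <- "aromaticity_broken"
    ok <- ok[!broke]
  }

  if (!is.null(retain_ring_size) && length(ok)) {
    had <- mapped_ring_atoms(g, mapped, retain_ring_size)
    if (length(had)) {
      noring <- vapply(ok, function(k) {
        gp <- list(B = raw[[k]])
        rings <- graph_rings(raw[[k]])
        !all(vapply(had, function(a) {
          any(vapply(rings, function(r) a %in% r && length(r) == retain_ring_size,
                     TRUE))
        }, TRUE))
      }, TRUE)
      status[ok[noring]] <- "ring_lost"
      ok <- ok[!noring]
    }
  }

  if (remove_strained && length(ok)) {
    sm <- strained_motif_filter(res_smiles[ok])
    status[ok[!sm$pass]] <- "strained"
    ok <- ok[sm$pass]
  }

  out <- data.frame(index = seq_along(lib), smiles = res_smiles,
                    status = status, stringsAsFactors = FALSE)
  out$smiles[out$status != "ok"] <- NA_character_
  attr(out, "mapping") <- mapping
  out
}

mapped_ring_atoms <- function(g, mapped, size) {
  ring_atoms <- integer(0)
  for (r in g$rings) {
    if (length(r) == size) {
      ring_atoms <- union(ring_atoms, intersect(r, mapped))
    }
  }
  ring_atoms
}

as_transformation_list <- function(library) {
  if (is.list(library)) return(lapply(library, function(T) {
    storage.mode(T) <- "integer"; unclass(T)
  }))
  if (is.array(library) && length(dim(library)) == 3) {
    return(lapply(seq_len(dim(library)[3]), function(k) {
      T <- library[, , k]; storage.mode(T) <- "integer"; T
    }))
  }
  if (is.matrix(library)) {  # rows of upper-triangle entries over 8 atoms
    return(lapply(seq_len(nrow(library)), function(r) {
      tri_to_full(as.integer(library[r, ]), 8L)
    }))
  }
  stop("unsupported transformation library format")
}

#' Reaction centers matched to a diversification run
#'
#' Applies the surviving transformation indices to the simple eight-atom
#' amine-acid system of the same hybridization, yielding one reaction-center
#' structure per diversified product, order-aligned and deliberately not
#' deduplicated (in the substituted substrate the alpha and beta carbons are
#' not degenerate, so centers that coincide as molecules are still distinct
#' transformations).
#'
#' @param indices integer vector of transformation indices (e.g. rows of the
#'   [diversify()] output with `status == "ok"`).
#' @param library the same transformation library used for diversification.
#' @param template template name or system.
#' @return character vector of center SMILES, `NA` where the simple system
#'   itself rejects the transformation; same length and order as `indices`.
#' @export
generate_reaction_centers <- function(indices, library, template = "sp3_sp3") {
  lib <- as_transformation_list(library)
  tm <- if (is.character(template)) sm_templates()[[template]] else template
  raw <- vapply(indices, function(k) {
    B2 <- tm$B + lib[[k]]
    if (!validate_matrix(B2, tm$atoms)$valid) return(NA_character_)
    tri_to_smiles_cpp(matrix(tri_of(B2), nrow = 1), tm$atoms$symbols)
  }, "")
  out <- rep(NA_character_, length(indices))
  ok <- !is.na(raw)
  if (any(ok)) out[ok] <- canonical_smiles(raw[ok])
  out
}
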