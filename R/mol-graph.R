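# Internal molecule-graph representation for arbitrary (drug-like) molecules.
#
# A mol_graph is a plain list: n, symbols, B (kekulized integer bond matrix
# over heavy atoms), charge (formal charge per atom), aromatic_edges (logical
# matrix flagging bonds in aromatic rings), rings (list of atom-index cycles).
# Parsing goes through OpenBabel/ChemmineR so that standard SMILES dialects,
# kekulization and sanitization are handled by an established toolkit;
# aromatic-ring perception on top of the kekulized graph uses a simple Hueckel
# electron count documented in the methods vignette.

#' Parse a molecule into a heavy-atom graph
#'
#' @param smiles single SMILES string.
#' @return a list with elements `n`, `symbols`, `B` (kekulized bond-order
#'   matrix), `charge`, `aromatic_edges` (logical matrix), `rings` (list of
#'   atom-index vectors, smallest ring through each ring bond).
#' @keywords internal
mol_graph <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  molblock <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "SDF",
                                               paste0(smiles, " m"))),
    error = function(e) NULL
  )
  lines <- if (is.null(molblock)) character(0) else
    strsplit(molblock, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4) stop("could not parse SMILES: ", smiles)
  na <- suppressWarnings(as.integer(substr(lines[4], 1, 3)))
  nb <- suppressWarnings(as.integer(substr(lines[4], 4, 6)))
  if (is.na(na) || na < 1) stop("could not parse SMILES: ", smiles)
  if (na == 1L || nb == 0L) {
    # ChemmineR's SDF container misreads bond-free molblocks; the V2000
    # atom line layout is fixed, so read the degenerate case directly
    atom_lines <- lines[5:(4 + na)]
    symbols <- trimws(substr(atom_lines, 32, 34))
    charged <- grepl("\\[[^]]*[+-][^]]*\\]", smiles)
    g <- list(n = na, symbols = symbols,
              B = matrix(0L, na, na),
              charge = rep(if (charged) 1L else 0L, na))
    g$rings <- list()
    g$aromatic_edges <- matrix(FALSE, na, na)
    return(g)
  }
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::read.SDFset(lines)),
    error = function(e) NULL
  )
  if (is.null(sdf) || length(sdf) < 1L) {
    stop("could not parse SMILES: ", smiles)
  }
  sdf1 <- sdf[[1]]
  ab <- ChemmineR::atomblock(sdf1)
  bb <- ChemmineR::bondblock(sdf1)
  n <- nrow(ab)
  symbols <- sub("_.*$", "", rownames(ab))
  charge <- integer(n)
  if ("C6" %in% colnames(ab)) {
    # V2000 legacy charge codes: 1..3 are +3..+1, 5..7 are -1..-3
    code <- ab[, "C6"]
    charge <- ifelse(code == 0, 0L,
                     ifelse(code <= 3, 4L - as.integer(code),
                            ifelse(code >= 5, 4L - as.integer(code), 0L)))
  }
  B <- matrix(0L, n, n)
  # single-atom / bond-free molecules yield a degenerate bond block
  if (is.matrix(bb) && nrow(bb) > 0 && ncol(bb) >= 3) {
    for (r in seq_len(nrow(bb))) {
      i <- suppressWarnings(as.integer(bb[r, 1]))
      j <- suppressWarnings(as.integer(bb[r, 2]))
      o <- suppressWarnings(as.integer(bb[r, 3]))
      if (is.na(i) || is.na(j) || is.na(o) || i < 1 || j < 1) next
      B[i, j] <- B[j, i] <- o
    }
  }
  g <- list(n = n, symbols = symbols, B = B, charge = as.integer(charge))
  g$rings <- graph_rings(B)
  g$aromatic_edges <- perceive_aromatic(g)
  g
}

# Smallest ring through every ring bond (the "relevant rings" used for ring
# perception): for each non-tree edge family, the shortest cycle containing
# each edge, found by BFS in the graph with that edge removed.
graph_rings <- function(B) {
  n <- nrow(B)
  if (n < 3) return(list())
  adj <- lapply(seq_len(n), function(i) which(B[i, ] > 0))
  rings <- list()
  seen_keys <- character(0)
  for (i in seq_len(n)) {
    for (j in adj[[i]]) {
      if (j <= i) next
      # shortest path i -> j avoiding edge (i, j)
      prev <- rep(NA_integer_, n)
      dist <- rep(NA_integer_, n)
      dist[i] <- 0L
      queue <- i
      while (length(queue) && is.na(dist[j])) {
        u <- queue[[1]]
        queue <- queue[-1]
        for (v in adj[[u]]) {
          if ((u == i && v == j) || (u == j && v == i)) next
          if (is.na(dist[v])) {
            dist[v] <- dist[u] + 1L
            prev[v] <- u
            queue <- c(queue, v)
          }
        }
      }
      if (is.na(dist[j])) next  # bridge, not a ring bond
      path <- j
      while (path[[1]] != i) path <- c(prev[path[[1]]], path)
      key <- paste(sort(path), collapse = "-")
      if (!(key %in% seen_keys)) {
        seen_keys <- c(seen_keys, key)
        rings[[length(rings) + 1L]] <- path
      }
    }
  }
  rings
}

# Aromatic ring perception on the kekulized graph: a ring is flagged aromatic
# when every ring atom is conjugation-capable (carries a double bond, or is a
# N/O/S heteroatom donating a lone pair) and the Hueckel pi-electron count is
# 4k + 2. Bonds of aromatic rings are marked in a logical matrix.
perceive_aromatic <- function(g) {
  n <- g$n
  arom <- matrix(FALSE, n, n)
  for (ring in g$rings) {
    k <- length(ring)
    if (k < 5 || k > 7) next
    pi_e <- 0L
    ok <- TRUE
    for (a in ring) {
      deg2 <- sum(g$B[a, ] == 2)
      in_ring_double <- any(g$B[a, ring] == 2)
      if (deg2 >= 1L) {
        # sp2 atom: contributes one pi electron if its double bond lies in or
        # adjacent to the ring plane; exocyclic C=O carbons count as 1
        pi_e <- pi_e + if (in_ring_double) 1L else 0L
        if (!in_ring_double && g$symbols[a] == "C") {
          pi_e <- pi_e + 0L  # quinoid carbon, contributes no electron
        }
      } else if (g$symbols[a] %in% c("N", "O", "S")) {
        pi_e <- pi_e + 2L   # lone-pair donor
      } else {
        ok <- FALSE
        break
      }
    }
    if (ok && pi_e %% 4L == 2L) {
      for (e in seq_len(k)) {
        a <- ring[e]
        b <- ring[if (e == k) 1L else e + 1L]
        arom[a, b] <- arom[b, a] <- TRUE
      }
    }
  }
  arom
}

#' Number of rings of a molecule
#'
#' The cyclomatic ring count `E - V + C` over the heavy-atom skeleton (bond
#' multiplicity ignored), which equals the size of the smallest set of
#' smallest rings.
#'
#' @param x a SMILES string (vectorized), a `mol_system`, or a bond matrix.
#' @return integer vector of ring counts.
#' @examples
#' ring_count("c1ccccc1")        # 1
#' ring_count("CCC(=O)NCC")      # 0
#' @export
ring_count <- function(x) {
  if (inherits(x, "mol_system")) x <- list(x)
  if (is.character(x)) {
    return(vapply(x, function(s) {
      g <- mol_graph(s)
      matrix_ring_count(g$B)
    }, 1L, USE.NAMES = FALSE))
  }
  if (is.matrix(x)) return(matrix_ring_count(x))
  vapply(x, function(s) matrix_ring_count(s$B), 1L)
}

matrix_ring_count <- function(B) {
  E <- sum(B[upper.tri(B)] > 0)
  V <- nrow(B)
  C <- length(unique(comp_labels(B)))
  as.integer(E - V + C)
}

# igraph handle of a mol_graph with element vertex colors and bond-order edge
# colors; aromatic bonds get their own color when preserve_aromaticity is on.
mol_igraph <- function(g, preserve_aromaticity = TRUE) {
  edges <- which(g$B > 0 & upper.tri(g$B), arr.ind = TRUE)
  colors <- integer(nrow(edges))
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    colors[r] <- if (preserve_aromaticity && g$aromatic_edges[i, j]) {
      5L
    } else {
      g$B[i, j]
    }
  }
  ig <- igraph::make_empty_graph(n = g$n, directed = FALSE)
  if (nrow(edges)) {
    ig <- igraph::add_edges(ig, t(edges))
  }
  igraph::E(ig)$color <- colors
  # vertex colors: element index (stable small integers)
  eltab <- c(C = 1L, N = 2L, O = 3L, S = 4L, P = 5L, F = 6L, Cl = 7L,
             Br = 8L, I = 9L, B = 10L)
  vc <- eltab[g$symbols]
  vc[is.na(vc)] <- 11L
  igraph::V(ig)$color <- as.integer(vc)
  ig
}
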