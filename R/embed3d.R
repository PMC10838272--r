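# Deterministic 3D embedding for shape analysis.
#
# A light distance-geometry scheme: explicit hydrogens are added, idealized
# through-bond distances define a target matrix (bond lengths for 1-2 pairs,
# law-of-cosines distances at ideal angles for 1-3 pairs, shortest-path sums
# beyond), classical multidimensional scaling provides starting coordinates,
# and a short weighted stress-majorization polish enforces the local geometry.
# Every step is deterministic, so shape coordinates are exactly reproducible;
# the trade-off against stochastic conformer searches is that only one
# conformer per molecule is produced (flexible chains come out extended).

ideal_bond_length <- function(e1, e2, order) {
  key <- paste(sort(c(e1, e2)), collapse = "-")
  tab1 <- c("C-C" = 1.54, "C-N" = 1.47, "C-O" = 1.43, "N-O" = 1.40,
            "N-N" = 1.45, "O-O" = 1.48, "C-S" = 1.82, "C-F" = 1.35,
            "C-Cl" = 1.77, "C-Br" = 1.94, "C-I" = 2.14, "C-H" = 1.09,
            "H-N" = 1.01, "H-O" = 0.96, "H-S" = 1.34, "H-H" = 1.60,
            "C-P" = 1.84, "N-S" = 1.68, "O-S" = 1.43, "O-P" = 1.60)
  tab2 <- c("C-C" = 1.34, "C-N" = 1.28, "C-O" = 1.22, "N-O" = 1.21,
            "N-N" = 1.25, "O-S" = 1.43)
  tab3 <- c("C-C" = 1.20, "C-N" = 1.16, "N-N" = 1.10)
  v <- switch(order, `1` = tab1[key], `2` = tab2[key], `3` = tab3[key],
              tab1[key])
  if (is.na(v)) v <- 1.5
  unname(v)
}

default_valence <- c(C = 4L, N = 3L, O = 2L, S = 2L, P = 3L, F = 1L,
                     Cl = 1L, Br = 1L, I = 1L, B = 3L, H = 1L)

# hydrogen-completed graph: symbols, bond matrix with orders, per-atom degree
with_hydrogens <- function(g) {
  nh <- vapply(seq_len(g$n), function(a) {
    val <- default_valence[g$symbols[a]]
    if (is.na(val)) return(0L)
    max(0L, as.integer(val) - as.integer(sum(g$B[a, ])))
  }, 1L)
  ntot <- g$n + sum(nh)
  B <- matrix(0L, ntot, ntot)
  B[seq_len(g$n), seq_len(g$n)] <- g$B
  symbols <- c(g$symbols, rep("H", sum(nh)))
  at <- g$n
  for (a in seq_len(g$n)) {
    if (nh[a] > 0) {
      for (k in seq_len(nh[a])) {
        at <- at + 1L
        B[a, at] <- B[at, a] <- 1L
      }
    }
  }
  list(n = ntot, symbols = symbols, B = B, n_heavy = g$n)
}

# target distances: bonds, then geminal (1-3) via ideal angles, then weighted
# shortest paths through the bond-length graph
target_distances <- function(gh) {
  n <- gh$n
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      if (gh$B[i, j] > 0) {
        D[i, j] <- D[j, i] <- ideal_bond_length(gh$symbols[i], gh$symbols[j],
                                                gh$B[i, j])
      }
    }
  }
  # Floyd-Warshall on bonded distances
  for (k in seq_len(n)) {
    Dk <- outer(D[, k], D[k, ], `+`)
    upd <- Dk < D
    D[upd] <- Dk[upd]
  }
  # overwrite 1-3 pairs with law-of-cosines targets at the center's angle
  ang <- vapply(seq_len(n), function(a) {
    if (gh$symbols[a] == "H") return(109.47)
    orders <- gh$B[a, ]
    heavy_deg <- sum(orders > 0)
    if (any(orders >= 3) || (gh$symbols[a] == "C" && heavy_deg <= 2 &&
                             sum(orders == 2) >= 2)) return(180)
    if (any(orders == 2)) return(120)
    109.47
  }, 1)
  bonded <- gh$B > 0
  for (a in seq_len(n)) {
    nb <- which(bonded[a, ])
    if (length(nb) < 2) next
    th <- ang[a] * pi / 180
    for (x in seq_along(nb)) {
      for (y in seq_len(x - 1)) {
        i <- nb[x]; j <- nb[y]
        r1 <- ideal_bond_length(gh$symbols[a], gh$symbols[i], gh$B[a, i])
        r2 <- ideal_bond_length(gh$symbols[a], gh$symbols[j], gh$B[a, j])
        d13 <- sqrt(r1^2 + r2^2 - 2 * r1 * r2 * cos(th))
        if (d13 < D[i, j]) D[i, j] <- D[j, i] <- d13
      }
    }
  }
  D
}

# weighted stress majorization (SMACOF); deterministic given the start
majorize <- function(X, D, W, iters = 60) {
  n <- nrow(X)
  wsum <- rowSums(W)
  for (it in seq_len(iters)) {
    dX <- as.matrix(stats::dist(X))
    dX[dX < 1e-9] <- 1e-9
    R <- W * D / dX
    diag(R) <- 0
    # x_i <- mean_j of w_ij * (x_j moved to distance d_ij from x_i)
    X <- (W %*% X - R %*% X + rowSums(R) * X) / wsum
  }
  X
}

#' Deterministic 3D embedding of a molecule
#'
#' @param smiles single SMILES string.
#' @return list with `coords` (matrix, one row per atom incl. hydrogens),
#'   `symbols`, `stress` (bond-length RMS error, Angstrom), or `NULL` when
#'   the molecule cannot be parsed.
#' @keywords internal
embed3d <- function(smiles) {
  g <- tryCatch(mol_graph(smiles), error = function(e) NULL)
  if (is.null(g) || g$n < 1) return(NULL)
  gh <- with_hydrogens(g)
  if (gh$n == 1) {
    return(list(coords = matrix(0, 1, 3), symbols = gh$symbols, stress = 0))
  }
  D <- target_distances(gh)
  X <- suppressWarnings(stats::cmdscale(D, k = 3))
  if (ncol(X) < 3) X <- cbind(X, matrix(0, nrow(X), 3 - ncol(X)))
  # deterministic symmetry-breaking jitter so planar/linear starts can relax
  jit <- outer(seq_len(gh$n), 1:3, function(i, k) sin(i * k * 2.399) * 1e-3)
  X <- X + jit
  W <- 1 / pmax(D, 0.5)^2
  diag(W) <- 0
  # emphasize local geometry: bonds dominate the stress
  bondW <- matrix(0, gh$n, gh$n)
  bondW[gh$B > 0] <- 25
  W <- W + bondW
  X <- majorize(X, D, W, iters = 80)
  dX <- as.matrix(stats::dist(X))
  bonds <- which(gh$B > 0 & upper.tri(gh$B))
  stress <- sqrt(mean((dX[bonds] - D[bonds])^2))
  list(coords = X, symbols = gh$symbols, stress = stress)
}
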