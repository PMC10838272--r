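#' Exhaustively enumerate valence-legal bond matrices
#'
#' Generates every symmetric, zero-diagonal integer matrix over the atom array
#' that respects the per-pair caps `min(b_i, b_j)` and the per-atom total bond
#' order `t_i`. The all-zero matrix and disconnected systems are included: no
#' connectivity constraint is applied at this stage. Matrices are produced in
#' lexicographically ascending order of their row-major upper triangle, so two
#' runs emit identical sequences.
#'
#' For counting at scale use `mode = "count"`, which never materializes
#' matrices and also returns a tally of completions per value of the first
#' upper-triangle entry; a run can be partitioned (and resumed) by fixing that
#' entry via `first_entry`.
#'
#' @param atoms an [atom_array()].
#' @param mode `"systems"` returns a list of [mol_system()] objects (guarded
#'   by `max_n`); `"matrices"` returns the raw upper-triangle matrix;
#'   `"count"` returns the count.
#' @param max_n materialization guard for `"systems"`/`"matrices"` modes.
#' @param first_entry optional integer fixing the first upper-triangle entry
#'   (checkpoint/resume partition).
#' @return per `mode`: a list of systems, an integer matrix (one row per
#'   enumerated matrix), or a numeric count with attribute
#'   `first_entry_tally`.
#' @examples
#' enumerate_matrices(atom_array(c("C", "O")), mode = "count")  # 3
#' @export
enumerate_matrices <- function(atoms, mode = c("systems", "matrices", "count"),
                               max_n = 1e6, first_entry = NULL) {
  stopifnot(inherits(atoms, "atom_array"))
  mode <- match.arg(mode)
  if (mode == "count") {
    res <- count_matrices_cpp(atoms$t, atoms$b,
                              if (is.null(first_entry)) -1L else as.integer(first_entry))
    out <- res$count
    attr(out, "first_entry_tally") <- res$first_entry_tally
    return(out)
  }
  tri <- enumerate_matrices_cpp(atoms$t, atoms$b, max_n)
  if (!is.null(first_entry)) {
    keep <- if (ncol(tri) > 0) tri[, 1] == first_entry else rep(TRUE, nrow(tri))
    tri <- tri[keep, , drop = FALSE]
  }
  if (mode == "matrices") return(tri)
  lapply(seq_len(nrow(tri)), function(r) mol_system(atoms, tri[r, ]))
}

#' Count valence-legal bond matrices
#'
#' Streaming counter equivalent to `enumerate_matrices(mode = "count")`: the
#' two modes return identical totals by construction (one deterministic
#' depth-first pass). The attached `first_entry_tally` records completions per
#' value of the first matrix entry, the checkpoint grain for resumable runs.
#'
#' @param atoms an [atom_array()].
#' @return numeric count with attribute `first_entry_tally`.
#' @examples
#' count_matrices(atom_array(c("C", "N")))  # 4: bond order 0..3
#' @export
count_matrices <- function(atoms) {
  enumerate_matrices(atoms, mode = "count")
}

#' Brute-force enumeration oracle
#'
#' Independent reference implementation for small systems: every assignment of
#' the upper-triangle entries in `0..max(b)` is generated by Cartesian
#' expansion and filtered through [validate_matrix()]. Refuses more than five
#' atoms (the candidate grid grows as `(max b + 1)^(n(n-1)/2)`). Intended for
#' exact set-equality checks against [enumerate_matrices()].
#'
#' @param atoms an [atom_array()].
#' @return integer matrix, one row per valid matrix (row-major upper
#'   triangle), in lexicographic order.
#' @export
brute_force_enumerate <- function(atoms) {
  stopifnot(inherits(atoms, "atom_array"))
  n <- n_atoms(atoms)
  if (n > 5L) stop("brute-force oracle is limited to 5 atoms")
  np <- (n * (n - 1L)) %/% 2L
  if (np == 0L) return(matrix(integer(0), nrow = 1, ncol = 0))
  mx <- max(atoms$b)
  grid <- as.matrix(expand.grid(replicate(np, 0:mx, simplify = FALSE)))
  dimnames(grid) <- NULL
  # pair index k -> (i, j) and per-pair entry cap
  pairs <- t(combn(n, 2L))
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  cap <- pmin(atoms$b[pairs[, 1]], atoms$b[pairs[, 2]])
  # incidence: entry k contributes to the row sums of both its atoms
  inc <- matrix(0L, np, n)
  for (k in seq_len(np)) inc[k, pairs[k, ]] <- 1L
  ok_cap <- rowSums(sweep(grid, 2L, cap, ">")) == 0L
  ok_row <- rowSums(sweep(grid %*% inc, 2L, atoms$t, ">")) == 0L
  out <- grid[ok_cap & ok_row, , drop = FALSE]
  storage.mode(out) <- "integer"
  out[do.call(order, lapply(seq_len(np), function(c) out[, c])), , drop = FALSE]
}
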