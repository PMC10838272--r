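# Plain-text serialization for bond matrices and reaction libraries.

#' Write and read bond-matrix collections as CSV
#'
#' The on-disk format is one matrix per row: the flattened lower triangle in
#' row order ((2,1), (3,1), (3,2), (4,1), ...) as integer columns, with a
#' header row naming each column by its atom pair and a leading `atoms`
#' column fixing the element symbols, so a file is self-describing.
#'
#' @param systems list of [mol_system()] objects on a shared atom array (or a
#'   single system).
#' @param path output CSV path.
#' @return `write_systems_csv` returns `path` invisibly; `read_systems_csv`
#'   returns a list of [mol_system()] objects.
#' @export
write_systems_csv <- function(systems, path) {
  if (inherits(systems, "mol_system")) systems <- list(systems)
  stopifnot(length(systems) > 0)
  symbols <- systems[[1]]$atoms$symbols
  n <- length(symbols)
  pairs <- if (n >= 2) {
    do.call(rbind, lapply(2:n, function(i) cbind(i, seq_len(i - 1))))
  } else matrix(integer(0), 0, 2)
  rows <- t(vapply(systems, function(s) {
    stopifnot(identical(s$atoms$symbols, symbols))
    vapply(seq_len(nrow(pairs)), function(k) {
      s$B[pairs[k, 1], pairs[k, 2]]
    }, 1L)
  }, integer(nrow(pairs))))
  if (nrow(pairs) == 1L) rows <- t(rows)
  df <- as.data.frame(rows)
  names(df) <- sprintf("b%d_%d", pairs[, 1], pairs[, 2])
  df <- cbind(atoms = paste(symbols, collapse = ""), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_systems_csv
#' @export
read_systems_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot("atoms" %in% names(df))
  symbols <- strsplit(df$atoms[1], "")[[1]]
  atoms <- atom_array(symbols)
  n <- length(symbols)
  cols <- setdiff(names(df), "atoms")
  idx <- do.call(rbind, lapply(cols, function(cn) {
    as.integer(strsplit(sub("^b", "", cn), "_")[[1]])
  }))
  lapply(seq_len(nrow(df)), function(r) {
    B <- matrix(0L, n, n)
    for (k in seq_along(cols)) {
      B[idx[k, 1], idx[k, 2]] <- B[idx[k, 2], idx[k, 1]] <-
        as.integer(df[r, cols[k]])
    }
    mol_system(atoms, B)
  })
}

#' Write and read a reaction library as CSV
#'
#' One record per transformation: the template id, the flattened lower
#' triangle of the transformation matrix (columns `t<i>_<j>`), its bond edit
#' distance, and the canonical SMILES of the product it generates from that
#' template.
#'
#' @param records data.frame with columns `template` (character) and
#'   `product` (SMILES), plus a list column `T` of 8 x 8 transformation
#'   matrices; or a list of such matrices with `template`/`product` supplied
#'   separately.
#' @param transformations list of 8 x 8 transformation matrices.
#' @param template template id per record (recycled if length 1).
#' @param product product SMILES per record.
#' @param path output CSV path.
#' @return `write_reaction_library` returns `path` invisibly;
#'   `read_reaction_library` returns a data.frame with the metadata columns
#'   plus a `T` list column of matrices.
#' @export
write_reaction_library <- function(transformations, template, product, path) {
  m <- length(transformations)
  template <- rep_len(template, m)
  stopifnot(length(product) == m)
  pairs <- do.call(rbind, lapply(2:8, function(i) cbind(i, seq_len(i - 1))))
  rows <- t(vapply(transformations, function(T) {
    vapply(seq_len(nrow(pairs)), function(k) {
      as.integer(T[pairs[k, 1], pairs[k, 2]])
    }, 1L)
  }, integer(nrow(pairs))))
  df <- as.data.frame(rows)
  names(df) <- sprintf("t%d_%d", pairs[, 1], pairs[, 2])
  dist <- vapply(transformations, bond_edit_distance, 1L)
  df <- cbind(template = template, df, edit_distance = dist,
              product = product)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reaction_library
#' @export
read_reaction_library <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tcols <- grep("^t[0-9]+_[0-9]+$", names(df), value = TRUE)
  idx <- do.call(rbind, lapply(tcols, function(cn) {
    as.integer(strsplit(sub("^t", "", cn), "_")[[1]])
  }))
  Ts <- lapply(seq_len(nrow(df)), function(r) {
    T <- matrix(0L, 8, 8)
    for (k in seq_along(tcols)) {
      T[idx[k, 1], idx[k, 2]] <- T[idx[k, 2], idx[k, 1]] <-
        as.integer(df[r, tcols[k]])
    }
    T
  })
  out <- df[, setdiff(names(df), tcols), drop = FALSE]
  out$T <- Ts
  out
}
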