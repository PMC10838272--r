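#' Ring-count / edit-distance funnel filter
#'
#' Removes products that are structurally improbable or synthetically remote:
#' anything with more than `max_rings` rings, or needing more than `max_edits`
#' bond edits from the amine-acid starting materials. Both thresholds are
#' inclusive ("more than" is eliminated). The filter is idempotent and
#' monotone in both thresholds.
#'
#' @param records data.frame with columns `rings` and
#'   `min_bond_edit_distance` (as produced by [product_census()]).
#' @param max_rings maximum ring count kept, default 4.
#' @param max_edits maximum bond edit distance kept, default 6.
#' @return the surviving subset, with dropped-record counts in attributes
#'   `n_dropped_rings` and `n_dropped_edits`.
#' @export
funnel_filter <- function(records, max_rings = 4, max_edits = 6) {
  need <- c("rings", "min_bond_edit_distance")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stop("records lack required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- !stats::complete.cases(records[, need])
  if (any(bad)) {
    warning(sum(bad), " record(s) with missing fields rejected")
    records <- records[!bad, , drop = FALSE]
  }
  keep_r <- records$rings <= max_rings
  keep_e <- records$min_bond_edit_distance <= max_edits
  out <- records[keep_r & keep_e, , drop = FALSE]
  attr(out, "n_dropped_rings") <- sum(!keep_r)
  attr(out, "n_dropped_edits") <- sum(!keep_e)
  out
}

#' Strained-motif structural filter
#'
#' Flags molecules matching any pattern in a SMARTS list of strained ring
#' motifs: bridgehead (anti-Bredt) alkenes, cumulated or triple bonds inside
#' small rings, and stacked small-ring fusions. The list ships as an editable
#' configuration file (`inst/extdata/strained_motifs.smarts`) since no single
#' canonical set exists; matching runs through OpenBabel.
#'
#' @param smiles character vector of molecules.
#' @param patterns data.frame with columns `smarts` and `label`, default the
#'   shipped list via [strained_motif_patterns()].
#' @return data.frame with columns `smiles`, `pass` (logical) and `motif`
#'   (first matched label or `NA`).
#' @examples
#' \donttest{
#' strained_motif_filter(c("C1CC2CC1C=C2", "C1=CC2CCC1C2"))$pass
#' }
#' @export
strained_motif_filter <- function(smiles, patterns = strained_motif_patterns()) {
  stopifnot(is.character(smiles), all(c("smarts", "label") %in% names(patterns)))
  hit <- rep(NA_character_, length(smiles))
  for (r in seq_len(nrow(patterns))) {
    m <- smarts_match(smiles, patterns$smarts[r])
    new_hit <- m & is.na(hit)
    hit[new_hit] <- patterns$label[r]
  }
  data.frame(smiles = smiles, pass = is.na(hit), motif = hit,
             stringsAsFactors = FALSE)
}

#' Shipped strained-motif SMARTS list
#'
#' @return data.frame with columns `smarts`, `label`.
#' @export
strained_motif_patterns <- function() {
  path <- system.file("extdata", "strained_motifs.smarts", package = "rxnspace")
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[ \t]+")
  df <- data.frame(smarts = vapply(parts, `[[`, "", 1L),
                   label = vapply(parts, function(p) paste(p[-1], collapse = " "), ""),
                   stringsAsFactors = FALSE)
  # validate all patterns up front: a broken config should fail loudly
  probe <- smarts_match("CC", df$smarts[1])
  df
}

# batch SMARTS matching through the obabel filter interface; returns a logical
# per input molecule (indices survive via per-line titles)
smarts_match <- function(smiles, smarts) {
  n <- length(smiles)
  if (n == 0L) return(logical(0))
  fin <- tempfile(fileext = ".smi")
  fout <- tempfile(fileext = ".smi")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(paste(smiles, seq_len(n)), fin)
  run_obabel(c(fin, "-osmi", "-e", "-O", fout,
               "--filter", shQuote(paste0("s='", smarts, "'"))))
  out <- rep(FALSE, n)
  if (file.exists(fout)) {
    lines <- readLines(fout, warn = FALSE)
    for (p in strsplit(trimws(lines[nzchar(lines)]), "[ \t]+")) {
      if (length(p) >= 2) {
        idx <- suppressWarnings(as.integer(p[[2]]))
        if (!is.na(idx)) out[idx] <- TRUE
      }
    }
  }
  out
}

#' Check that substrate aromaticity survives a transformation
#'
#' True when every aromatic ring of the substrate maps onto an aromatic ring
#' of the product over the same atom indices (atom indexing must be shared,
#' as it is for products generated by [diversify()]). Molecules without
#' aromatic rings pass vacuously.
#'
#' @param substrate,product `mol_graph`-compatible inputs: SMILES strings or
#'   graphs with identical atom indexing.
#' @return logical.
#' @export
aromaticity_preserved <- function(substrate, product) {
  gs <- if (is.character(substrate)) mol_graph(substrate) else substrate
  gp <- if (is.character(product)) mol_graph(product) else product
  for (ring in gs$rings) {
    if (!ring_is_aromatic(gs, ring)) next
    if (max(ring) > gp$n) return(FALSE)
    if (!ring_is_aromatic(gp, ring)) return(FALSE)
  }
  TRUE
}

ring_is_aromatic <- function(g, ring) {
  k <- length(ring)
  all(vapply(seq_len(k), function(e) {
    a <- ring[e]
    b <- ring[if (e == k) 1L else e + 1L]
    g$B[a, b] > 0 && g$aromatic_edges[a, b]
  }, TRUE))
}

#' Composition filter for library polarity matching
#'
#' Keeps molecules with fewer than `max_heavy` heavy atoms and fewer than
#' `max_NO` nitrogen-plus-oxygen atoms (strict inequalities).
#'
#' @param smiles character vector.
#' @param max_heavy heavy-atom bound (exclusive), default 13.
#' @param max_NO combined N+O bound (exclusive), default 2.
#' @return the surviving SMILES subset.
#' @examples
#' composition_filter(c("CCN", "CCON"), max_heavy = 13, max_NO = 2)
#' @export
composition_filter <- function(smiles, max_heavy = 13, max_NO = 2) {
  keep <- vapply(smiles, function(s) {
    g <- tryCatch(mol_graph(s), error = function(e) NULL)
    if (is.null(g)) return(FALSE)
    g$n < max_heavy && sum(g$symbols %in% c("N", "O")) < max_NO
  }, TRUE, USE.NAMES = FALSE)
  smiles[keep]
}
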