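#' Substructure frequencies of products in a compound library
#'
#' Counts, for every (query, compound) pair, the number of symmetry-distinct
#' embeddings of the query's heavy-atom graph in the compound: matches are
#' subgraph monomorphisms with exact element and bond-order agreement,
#' deduplicated by matched atom set so graph automorphisms are not
#' double-counted. With `preserve_aromaticity = TRUE` (default) aromatic
#' bonds carry their own bond class on both sides, so an aliphatic query bond
#' never matches along an aromatic ring -- kekulized matching
#' (`FALSE`) is strictly more permissive.
#'
#' @param queries character vector of query SMILES (e.g. enumerated
#'   products).
#' @param library character vector of compound SMILES, optionally named with
#'   compound ids.
#' @param preserve_aromaticity logical, default `TRUE`.
#' @return data.frame with columns `query`, `compound`, `count` (only nonzero
#'   rows) plus attribute `totals`: a per-query total frequency table.
#'   Unparsable entries on either side are logged via message and skipped.
#' @export
substructure_frequencies <- function(queries, library,
                                     preserve_aromaticity = TRUE) {
  if (is.null(names(library))) {
    names(library) <- paste0("compound_", seq_along(library))
  }
  qg <- lapply(queries, function(s) tryCatch(mol_graph(s), error = function(e) NULL))
  lg <- lapply(library, function(s) tryCatch(mol_graph(s), error = function(e) NULL))
  badq <- vapply(qg, is.null, TRUE)
  badl <- vapply(lg, is.null, TRUE)
  if (any(badq)) message(sum(badq), " unparsable query structure(s) skipped")
  if (any(badl)) message(sum(badl), " unparsable library structure(s) skipped")

  rows <- list()
  for (qi in seq_along(queries)) {
    if (badq[qi]) next
    for (li in seq_along(library)) {
      if (badl[li]) next
      cnt <- count_embeddings(qg[[qi]], lg[[li]], preserve_aromaticity)
      if (cnt > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          query = queries[qi], compound = names(library)[li], count = cnt,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query = character(0), compound = character(0),
               count = integer(0), stringsAsFactors = FALSE)
  totals <- stats::setNames(rep(0L, length(queries)), queries)
  if (nrow(out)) {
    agg <- stats::aggregate(count ~ query, out, sum)
    totals[agg$query] <- agg$count
  }
  attr(out, "totals") <- totals
  out
}

# Symmetry-distinct embeddings of the query graph in the target: subgraph
# monomorphisms (LAD, element-restricted domains), kept when every query bond
# is compatible with the mapped target bond, then deduplicated by matched
# atom set so automorphic images count once. Bond compatibility: exact class
# agreement; in kekulized mode (preserve_aromaticity = FALSE on both graphs)
# an aromatic bond additionally matches a single or double query bond, which
# is what lets saturated queries match along aromatic rings.
count_embeddings <- function(q, t, preserve_aromaticity) {
  if (q$n > t$n) return(0L)
  qig <- mol_igraph(q, preserve_aromaticity = TRUE)
  tig <- mol_igraph(t, preserve_aromaticity = TRUE)
  domains <- lapply(seq_len(q$n), function(i) {
    which(igraph::V(tig)$color == igraph::V(qig)$color[i])
  })
  if (any(vapply(domains, length, 1L) == 0L)) return(0L)
  maps <- tryCatch(
    igraph::subgraph_isomorphisms(pattern = qig, target = tig,
                                  method = "lad", domains = domains,
                                  induced = FALSE),
    error = function(e) list())
  if (!length(maps)) return(0L)
  qedges <- which(q$B > 0 & upper.tri(q$B), arr.ind = TRUE)
  ok_edge <- function(qo, qa, to, ta) {
    if (preserve_aromaticity) {
      if (qa || ta) return(qa && ta)
      return(qo == to)
    }
    if (qa && ta) return(TRUE)
    if (ta) return(qo %in% c(1L, 2L))
    if (qa) return(to %in% c(1L, 2L))
    qo == to
  }
  good <- vapply(maps, function(m) {
    m <- as.integer(m)
    all(vapply(seq_len(nrow(qedges)), function(e) {
      i <- qedges[e, 1]; j <- qedges[e, 2]
      ti <- m[i]; tj <- m[j]
      if (t$B[ti, tj] == 0L) return(FALSE)
      ok_edge(q$B[i, j], q$aromatic_edges[i, j],
              t$B[ti, tj], t$aromatic_edges[ti, tj])
    }, TRUE))
  }, TRUE)
  maps <- maps[good]
  if (!length(maps)) return(0L)
  keys <- vapply(maps, function(m) paste(sort(as.integer(m)), collapse = ","), "")
  length(unique(keys))
}

#' Group query frequencies by elemental composition
#'
#' Buckets queries into the four composition groups of the amine-acid system
#' (`C`, `C+N`, `C+O`, `C+N+O`) and ranks them by total frequency within each
#' group.
#'
#' @param freq result of [substructure_frequencies()] (its `totals` attribute
#'   is used; a named numeric vector also works).
#' @param top_k ranks reported per group, default 3; `Inf` for all.
#' @return data.frame with columns `group`, `rank`, `query`, `total`.
#' @export
group_by_composition <- function(freq, top_k = 3) {
  totals <- if (is.data.frame(freq)) attr(freq, "totals") else freq
  stopifnot(!is.null(totals), !is.null(names(totals)))
  grp <- vapply(names(totals), function(s) {
    g <- tryCatch(mol_graph(s), error = function(e) NULL)
    if (is.null(g)) return(NA_character_)
    has_n <- "N" %in% g$symbols
    has_o <- "O" %in% g$symbols
    if (has_n && has_o) "C+N+O" else if (has_n) "C+N" else if (has_o) "C+O" else "C"
  }, "")
  out <- NULL
  for (g in c("C", "C+N", "C+O", "C+N+O")) {
    sel <- which(grp == g)
    if (!length(sel)) next
    ord <- sel[order(-totals[sel], names(totals)[sel])]
    ord <- head(ord, top_k)
    out <- rbind(out, data.frame(
      group = g, rank = seq_along(ord), query = names(totals)[ord],
      total = unname(totals[ord]), stringsAsFactors = FALSE))
  }
  if (is.null(out)) {
    out <- data.frame(group = character(0), rank = integer(0),
                      query = character(0), total = numeric(0))
  }
  out
}

#' Export chord-diagram link data
#'
#' Writes (and returns) the link table behind a chord diagram connecting
#' library compounds to the enumerated products found in them: queries are
#' sorted by increasing bond edit distance from the amine-acid starting
#' materials (ties broken by canonical SMILES), only nonzero links are
#' emitted, and frequencies are banded into the color classes
#' `1`, `2`-`10`, `>10`.
#'
#' @param freq result of [substructure_frequencies()].
#' @param edit_distances named integer vector: minimal bond edit distance per
#'   query SMILES (every query must be present).
#' @param path optional output CSV path.
#' @return data.frame with columns `query`, `query_position`,
#'   `edit_distance`, `compound`, `count`, `band`, sorted by
#'   `query_position`.
#' @export
chord_export <- function(freq, edit_distances, path = NULL) {
  stopifnot(is.data.frame(freq))
  queries <- unique(freq$query)
  missing_d <- setdiff(queries, names(edit_distances))
  if (length(missing_d)) {
    stop("no edit distance for query: ", paste(missing_d, collapse = ", "))
  }
  all_q <- names(edit_distances)
  ord <- order(edit_distances, all_q)
  pos <- stats::setNames(seq_along(all_q), all_q[ord])
  out <- freq
  out$edit_distance <- as.integer(edit_distances[out$query])
  out$query_position <- as.integer(pos[out$query])
  out$band <- cut(out$count, breaks = c(0, 1, 10, Inf),
                  labels = c("1", "2-10", ">10"))
  out <- out[order(out$query_position, out$compound),
             c("query", "query_position", "edit_distance", "compound",
               "count", "band")]
  rownames(out) <- NULL
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
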