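#' Physicochemical descriptor panel
#'
#' Computes, per molecule: hydrogen-bond donors and acceptors (HBD/HBA),
#' molecular weight (MW, g/mol), topological polar surface area (PSA, A^2),
#' fraction of sp3 carbons (FSP3), a drug-likeness desirability score (QED,
#' in `[0, 1]`), the octanol-water partition coefficient (LogP), rotatable
#' bond count (ROTB) and ring count. HBD/HBA/MW/PSA/LogP/ROTB come from
#' OpenBabel's descriptor implementations; FSP3, ring count and the QED-style
#' aggregate are computed here (see the methods vignette for definitions and
#' for the all-heavy-atom FSP3 variant in column `FSP3_heavy`).
#'
#' @param smiles character vector.
#' @return data.frame with one row per input; unparsable molecules yield a row
#'   of `NA`s with `ok = FALSE`, and the pipeline continues.
#' @examples
#' \donttest{
#' compute_descriptors("CCC(=O)NCC")$HBD   # 1
#' }
#' @export
compute_descriptors <- function(smiles) {
  n <- length(smiles)
  out <- data.frame(
    smiles = smiles, ok = FALSE,
    HBD = NA_real_, HBA = NA_real_, MW = NA_real_, PSA = NA_real_,
    FSP3 = NA_real_, FSP3_heavy = NA_real_, QED = NA_real_,
    LogP = NA_real_, ROTB = NA_real_, rings = NA_integer_,
    stringsAsFactors = FALSE
  )
  if (n == 0L) return(out)
  fin <- tempfile(fileext = ".smi")
  fout <- tempfile(fileext = ".txt")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(paste(smiles, seq_len(n)), fin)
  run_obabel(c(fin, "-osmi", "-e", "-O", fout, "--append",
               shQuote("HBD HBA1 MW TPSA logP rotors")))
  if (file.exists(fout)) {
    for (p in strsplit(trimws(readLines(fout, warn = FALSE)), "\t")) {
      if (length(p) < 2) next
      fields <- strsplit(p[[2]], "[ \t]+")[[1]]
      idx <- suppressWarnings(as.integer(fields[[1]]))
      if (is.na(idx) || length(fields) < 7) next
      vals <- suppressWarnings(as.numeric(fields[2:7]))
      out$HBD[idx] <- vals[1]; out$HBA[idx] <- vals[2]
      out$MW[idx] <- vals[3]; out$PSA[idx] <- vals[4]
      out$LogP[idx] <- vals[5]; out$ROTB[idx] <- vals[6]
      out$ok[idx] <- TRUE
    }
  }
  for (i in which(out$ok)) {
    g <- tryCatch(mol_graph(smiles[i]), error = function(e) NULL)
    if (is.null(g)) { out$ok[i] <- FALSE; next }
    out$rings[i] <- matrix_ring_count(g$B)
    fs <- fsp3(g)
    out$FSP3[i] <- fs["carbon"]
    out$FSP3_heavy[i] <- fs["heavy"]
  }
  arom_rings <- vapply(seq_len(n), function(i) {
    if (!out$ok[i]) return(NA_integer_)
    g <- tryCatch(mol_graph(smiles[i]), error = function(e) NULL)
    if (is.null(g)) return(NA_integer_)
    sum(vapply(g$rings, function(r) ring_is_aromatic(g, r), TRUE))
  }, 1L)
  out$QED <- qed_score(out, arom_rings)
  out
}

# fraction of sp3 carbons: carbons whose bonds are all single (the standard
# definition), plus a variant with all heavy atoms in the denominator
fsp3 <- function(g) {
  carbons <- which(g$symbols == "C")
  if (!length(carbons)) return(c(carbon = 0, heavy = 0))
  sp3 <- vapply(carbons, function(a) all(g$B[a, ] <= 1), TRUE)
  c(carbon = sum(sp3) / length(carbons),
    heavy = sum(sp3) / g$n)
}

# Drug-likeness desirability aggregate in the spirit of the quantitative
# estimate of drug-likeness: geometric mean of per-property desirability
# functions. Each desirability is a smooth unimodal curve centred on the
# typical oral-drug range of that property; parameters are package defaults
# documented in the methods vignette, not a reproduction of any fitted set.
qed_score <- function(d, arom_rings) {
  desir <- function(x, mu, sig) exp(-((x - mu)^2) / (2 * sig^2))
  desir_low <- function(x, edge, width) 1 / (1 + exp((x - edge) / width))
  terms <- cbind(
    desir(d$MW, 300, 150),
    desir(d$LogP, 2.5, 2.5),
    desir_low(d$HBA, 7, 1.5),
    desir_low(d$HBD, 4, 1),
    desir(d$PSA, 70, 60),
    desir_low(d$ROTB, 8, 2),
    desir(arom_rings, 1.5, 1.5)
  )
  apply(terms, 1, function(r) {
    if (anyNA(r)) return(NA_real_)
    exp(mean(log(pmax(r, 1e-6))))
  })
}

#' Normalized principal-moment-of-inertia shape coordinates
#'
#' Embeds each molecule in 3D (hydrogens added, deterministic
#' distance-geometry embedding: classical scaling of idealized through-bond
#' distances with stress-majorization refinement), computes the three
#' principal moments of inertia from atomic masses and coordinates, sorts
#' them ascending and reports NPR1 = PMI1/PMI3 and NPR2 = PMI2/PMI3.
#' Successful embeddings satisfy NPR1 <= NPR2 <= 1 and NPR1 + NPR2 >= 1:
#' rods sit near (0, 1), discs near (0.5, 0.5), spheres near (1, 1). An
#' embedding failure -- an unparsable structure, or local geometry that
#' cannot be satisfied within tolerance, as happens in highly strained
#' cages -- is reported as `embed_status = "failed"`, never an error.
#'
#' @param smiles character vector.
#' @param seed integer recorded in the result for provenance; the embedder
#'   itself is deterministic.
#' @param stress_tol bond-length RMS error (Angstrom) above which an
#'   embedding is reported as failed, default 0.3.
#' @return data.frame with columns `smiles`, `NPR1`, `NPR2`, `embed_status`.
#' @examples
#' \donttest{
#' compute_npr("CC#CC#CC")  # rod-like: NPR1 near 0, NPR2 near 1
#' }
#' @export
compute_npr <- function(smiles, seed = 42L, stress_tol = 0.3) {
  n <- length(smiles)
  out <- data.frame(smiles = smiles, NPR1 = NA_real_, NPR2 = NA_real_,
                    embed_status = "failed", stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    emb <- embed3d(smiles[i])
    if (is.null(emb) || emb$stress > stress_tol) next
    pmi <- principal_moments(emb$coords, emb$symbols)
    if (is.null(pmi) || pmi[3] <= 0) next
    out$NPR1[i] <- pmi[1] / pmi[3]
    out$NPR2[i] <- pmi[2] / pmi[3]
    out$embed_status[i] <- "ok"
  }
  attr(out, "seed") <- seed
  out
}

atomic_masses <- c(H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
                   F = 18.998, P = 30.974, S = 32.06, Cl = 35.45,
                   Br = 79.904, I = 126.904)

principal_moments <- function(coords, symbols) {
  m <- atomic_masses[symbols]
  if (anyNA(m) || nrow(coords) < 2) return(NULL)
  ctr <- colSums(coords * m) / sum(m)
  x <- sweep(coords, 2, ctr)
  Ixx <- sum(m * (x[, 2]^2 + x[, 3]^2))
  Iyy <- sum(m * (x[, 1]^2 + x[, 3]^2))
  Izz <- sum(m * (x[, 1]^2 + x[, 2]^2))
  Ixy <- -sum(m * x[, 1] * x[, 2])
  Ixz <- -sum(m * x[, 1] * x[, 3])
  Iyz <- -sum(m * x[, 2] * x[, 3])
  I <- matrix(c(Ixx, Ixy, Ixz, Ixy, Iyy, Iyz, Ixz, Iyz, Izz), 3, 3)
  sort(eigen(I, symmetric = TRUE, only.values = TRUE)$values)
}

#' Whole-molecule versus reaction-center property deltas
#'
#' Joins the diversified-substrate products and their matched reaction-center
#' structures by transformation index, computes each descriptor's shift
#' relative to the corresponding amide product on both sides, and returns the
#' joint table behind property-modulation plots: one row per transformation,
#' `delta_full_*` for the whole molecule, `delta_center_*` for the eight-atom
#' reaction center.
#'
#' @param substrate_products data.frame with columns `index`, `smiles`
#'   (diversified whole molecules).
#' @param center_products data.frame with columns `index`, `smiles` (matched
#'   reaction centers).
#' @param reference_index the transformation index of the amide reference.
#' @return data.frame of per-transformation deltas; unpaired indices are
#'   dropped with a message.
#' @export
property_deltas <- function(substrate_products, center_products,
                            reference_index) {
  stopifnot(all(c("index", "smiles") %in% names(substrate_products)),
            all(c("index", "smiles") %in% names(center_products)))
  common <- intersect(substrate_products$index, center_products$index)
  dropped <- length(setdiff(union(substrate_products$index, center_products$index),
                            common))
  if (dropped > 0) message(dropped, " unpaired transformation(s) skipped")
  if (!(reference_index %in% common)) {
    stop("reference transformation is not present on both sides")
  }
  sp <- substrate_products[match(common, substrate_products$index), ]
  cp <- center_products[match(common, center_products$index), ]
  dfull <- compute_descriptors(sp$smiles)
  dctr <- compute_descriptors(cp$smiles)
  props <- c("HBD", "HBA", "MW", "PSA", "FSP3", "QED", "LogP", "ROTB", "rings")
  ref <- which(common == reference_index)
  out <- data.frame(index = common)
  for (p in props) {
    out[[paste0("delta_full_", p)]] <- dfull[[p]] - dfull[[p]][ref]
    out[[paste0("delta_center_", p)]] <- dctr[[p]] - dctr[[p]][ref]
  }
  out
}
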