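#' Run the enumeration-to-analysis pipeline
#'
#' Orchestrates the funnel end to end for a C/N/O atom array: exhaustive
#' matrix count, degeneracy orbit count, unique-product census, ring/edit
#' funnel filter, descriptor panel and shape coordinates, writing
#' reproducible CSVs plus a manifest of counts at every stage. Rerunning with
#' the same configuration produces byte-identical outputs.
#'
#' @param config list with elements `symbols` (character, default the
#'   eight-atom array), `min_heavy_atoms` (4), `max_rings` (4), `max_edits`
#'   (6), `residual` (`"fragmented"`), `seed` (42), `property_rows` (cap on
#'   rows scored with descriptors/NPR, default 200; `Inf` scores everything).
#' @param out_dir output directory, created if needed.
#' @return invisibly, the manifest data.frame. Files written:
#'   `smiles_min_dist_natoms.csv` (product table),
#'   `products_props.csv`, `products_pmi.csv`, `manifest.csv`.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- utils::modifyList(list(
    symbols = c("C", "C", "C", "C", "C", "N", "O", "O"),
    min_heavy_atoms = 4, max_rings = 4, max_edits = 6,
    residual = "fragmented", seed = 42L, property_rows = 200
  ), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  atoms <- atom_array(cfg$symbols)

  n_mat <- as.numeric(count_matrices(atoms))
  n_orb <- count_orbit_matrices(atoms)
  census <- product_census(atoms, min_heavy_atoms = cfg$min_heavy_atoms,
                           residual = cfg$residual)
  filtered <- funnel_filter(census, max_rings = cfg$max_rings,
                            max_edits = cfg$max_edits)

  prod_path <- file.path(out_dir, "smiles_min_dist_natoms.csv")
  utils::write.csv(
    census[, c("smiles", "n_heavy_atoms", "min_bond_edit_distance", "rings")],
    prod_path, row.names = FALSE)

  scored <- head(filtered, cfg$property_rows)
  props <- compute_descriptors(scored$smiles)
  utils::write.csv(props, file.path(out_dir, "products_props.csv"),
                   row.names = FALSE)
  pmi <- compute_npr(scored$smiles, seed = cfg$seed)
  utils::write.csv(pmi, file.path(out_dir, "products_pmi.csv"),
                   row.names = FALSE)

  manifest <- data.frame(
    stage = c("matrices", "degeneracy_orbits", "unique_products",
              "filtered_products", "descriptor_rows", "npr_ok"),
    count = c(n_mat, n_orb, nrow(census), nrow(filtered), nrow(props),
              sum(pmi$embed_status == "ok")))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Generate in-repo fixtures
#'
#' Emits small plain-text fixtures so every pipeline stage is testable
#' offline: `toy-system` writes atom arrays with brute-force-verified matrix
#' counts; `toy-drug-library` writes a 50-molecule drug-like SMILES library
#' (a synthetic stand-in for a licensed drug database); `worked-examples`
#' writes the amide and Diels-Alder transformation matrices with their
#' expected bond edit distances.
#'
#' @param kind one of `"toy-system"`, `"toy-drug-library"`,
#'   `"worked-examples"`.
#' @param dir output directory.
#' @return character vector of files written.
#' @export
generate_fixtures <- function(kind = c("toy-system", "toy-drug-library",
                                       "worked-examples"), dir) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (kind == "toy-system") {
    systems <- list(c("C", "O"), c("C", "N"), c("O", "O"), c("C", "C", "O"),
                    c("C", "C", "N", "O"))
    rows <- lapply(systems, function(sym) {
      a <- atom_array(sym)
      data.frame(atoms = paste(sym, collapse = ""),
                 n_matrices = nrow(brute_force_enumerate(a)))
    })
    path <- file.path(dir, "toy_system_counts.csv")
    utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
    return(path)
  }
  if (kind == "toy-drug-library") {
    path <- file.path(dir, "toy_drug_library.csv")
    utils::write.csv(toy_drug_library(), path, row.names = FALSE)
    return(path)
  }
  amide <- amide_transformation()
  da <- diels_alder_example()
  path1 <- file.path(dir, "amide_transformation.csv")
  utils::write.csv(data.frame(tri = tri_of(amide),
                              expected_distance = 2L), path1, row.names = FALSE)
  path2 <- file.path(dir, "diels_alder_transformation.csv")
  utils::write.csv(data.frame(tri = tri_of(da),
                              expected_distance = 6L), path2, row.names = FALSE)
  c(path1, path2)
}

#' The Diels-Alder transformation on a six-carbon system
#'
#' Butadiene (atoms 1-4) plus ethylene (atoms 5-6) closing to cyclohexene:
#' two sigma bonds form (4-5, 6-1), the diene termini lose a bond order each,
#' the diene center gains one, and the dienophile double bond drops to
#' single. Six unit bond edits in total -- the textbook example that bond
#' edit distance does not track mechanistic step count (the reaction is one
#' concerted step), unlike a direct C-N cross-coupling, a multi-step
#' catalytic cycle with edit distance 1.
#'
#' @return 6 x 6 `transformation_matrix`.
#' @export
diels_alder_example <- function() {
  sm <- matrix(0L, 6, 6)
  bond <- function(B, i, j, o) { B[i, j] <- B[j, i] <- as.integer(o); B }
  sm <- bond(sm, 1, 2, 2); sm <- bond(sm, 2, 3, 1); sm <- bond(sm, 3, 4, 2)
  sm <- bond(sm, 5, 6, 2)
  pr <- matrix(0L, 6, 6)
  pr <- bond(pr, 1, 2, 1); pr <- bond(pr, 2, 3, 2); pr <- bond(pr, 3, 4, 1)
  pr <- bond(pr, 4, 5, 1); pr <- bond(pr, 5, 6, 1); pr <- bond(pr, 6, 1, 1)
  derive_transformation(pr, sm)
}

#' Toy drug-like compound library
#'
#' Fifty structures: a core of familiar small-molecule drugs plus
#' systematically constructed drug-like amides, esters, ethers and amines
#' (ids prefixed `synth_`). Serves as the offline stand-in for a licensed
#' drug database in substructure-search examples and tests.
#'
#' @return data.frame with columns `id`, `smiles`.
#' @export
toy_drug_library <- function() {
  known <- c(
    aspirin = "CC(=O)Oc1ccccc1C(=O)O",
    paracetamol = "CC(=O)Nc1ccc(O)cc1",
    ibuprofen = "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
    caffeine = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
    nicotine = "CN1CCCC1c1cccnc1",
    benzocaine = "CCOC(=O)c1ccc(N)cc1",
    procaine = "CCN(CC)CCOC(=O)c1ccc(N)cc1",
    lidocaine = "CCN(CC)CC(=O)Nc1c(C)cccc1C",
    ethosuximide = "CCC1(C)CC(=O)NC1=O",
    valproate = "CCCC(CCC)C(=O)O",
    deet = "CCN(CC)C(=O)c1cccc(C)c1",
    phenacetin = "CCOc1ccc(NC(C)=O)cc1",
    salicylamide = "NC(=O)c1ccccc1O",
    benzamide = "NC(=O)c1ccccc1",
    gaba = "NCCCC(=O)O",
    putrescine_amide = "NCCCCNC(C)=O",
    levulinic = "CC(=O)CCC(=O)O",
    propranolol_core = "CC(C)NCC(O)COc1ccccc1"
  )
  synth <- c(
    "CCNC(C)=O", "CCCNC(C)=O", "CCNC(=O)CC", "CCCNC(=O)CC",
    "CCNC(=O)C(C)C", "CCCNC(=O)C(C)C", "CCNC(=O)c1ccccc1",
    "CCCNC(=O)c1ccccc1", "OCCNC(C)=O", "OCCNC(=O)CC",
    "OCCNC(=O)c1ccccc1", "C1CCCCC1NC(C)=O", "C1CCCCC1NC(=O)CC",
    "c1ccccc1NC(C)=O", "c1ccccc1NC(=O)CC", "c1ccccc1CCNC(C)=O",
    "c1ccccc1CCNC(=O)CC", "CCOC(=O)CC", "CCOC(=O)C(C)C",
    "CCOC(=O)c1ccccc1", "CCCOC(C)=O", "CCOCC", "CCOCCC", "CCCOCCO",
    "CCN(C)CC", "CCCN(C)C", "c1ccccc1CN(C)C", "CCNCCO",
    "CC(C)NC(=O)C1CCCC1", "CCNC(=O)Cc1ccco1", "OCCNC(=O)C(C)C",
    "CCCCNC(=O)CC"
  )
  data.frame(
    id = c(names(known), sprintf("synth_%02d", seq_along(synth))),
    smiles = unname(c(known, synth)),
    stringsAsFactors = FALSE
  )
}
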