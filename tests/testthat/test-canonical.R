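test_that("canonicalization under the degeneracy group has fixed points and 2-orbits", {
  a <- atom_array(c("C", "O", "O"), degeneracy_classes = list(1L, 2:3))
  # symmetric in the two oxygens: fixed point
  sym <- bondmat(3, list(c(1, 2, 1), c(1, 3, 1)))
  expect_equal(unname(canonical_under_group(sym, atoms = a)), sym)
  # asymmetric pair: both members map to one key
  b1 <- bondmat(3, list(c(1, 2, 2)))
  b2 <- bondmat(3, list(c(1, 3, 2)))
  k1 <- canonical_under_group(b1, atoms = a)
  k2 <- canonical_under_group(b2, atoms = a)
  expect_equal(unname(k1), unname(k2))
})

test_that("orbit counts agree between Burnside and brute-force partitioning", {
  a <- atom_array(c("C", "O", "O"), degeneracy_classes = list(1L, 2:3))
  mats <- brute_force_enumerate(a)
  keys <- apply(mats, 1, function(tri) {
    paste(canonical_under_group(rxnspace:::tri_to_full(as.integer(tri), 3),
                                atoms = a), collapse = ",")
  })
  expect_equal(as.numeric(count_orbit_matrices(a)), length(unique(keys)))
  expect_equal(count_orbit_matrices(a), count_orbit_matrices(a, method = "direct"))
})

test_that("orbit counting routes agree on larger degenerate arrays", {
  arr <- atom_array(c("C", "C", "N", "O", "O"))
  expect_equal(count_orbit_matrices(arr),
               count_orbit_matrices(arr, method = "direct"))
})

test_that("unique_products drops small fragments and collapses degenerate routes", {
  a <- atom_array(c("C", "C", "C", "C", "N"))
  # two routes to butane: bond chain 1-2-3-4 or 2-3-4 plus 1 at the other end;
  # the nitrogen stays disconnected (a lost NH3)
  s1 <- mol_system(a, bondmat(5, list(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1))))
  s2 <- mol_system(a, bondmat(5, list(c(1, 3, 1), c(3, 4, 1), c(4, 2, 1))))
  up <- unique_products(list(s1, s2), min_heavy_atoms = 4)
  expect_equal(nrow(up), 1L)
  expect_equal(up$smiles, canonical_smiles("CCCC"))
  expect_equal(up$n_heavy_atoms, 4L)
  # methane fragments (1 heavy atom) never survive the threshold
  s3 <- mol_system(a, bondmat(5, list(c(1, 2, 1))))
  expect_equal(nrow(unique_products(list(s3), min_heavy_atoms = 4)), 0L)
})

test_that("dedup is idempotent and the witness regenerates its product", {
  a <- atom_array(c("C", "C", "N", "O"))
  systems <- enumerate_matrices(a)
  up <- unique_products(systems, min_heavy_atoms = 4)
  # feeding the witnesses back in reproduces exactly the same table
  again <- unique_products(
    lapply(up$witness, function(B) mol_system(a, B)), min_heavy_atoms = 4)
  expect_setequal(again$smiles, up$smiles)
  for (r in seq_len(nrow(up))) {
    s <- mol_system(a, up$witness[[r]])
    lab <- system_components(s)
    sizes <- table(lab)
    big <- as.integer(names(sizes)[sizes >= 4])
    frags <- vapply(big, function(cm) {
      idx <- which(lab == cm)
      canonical_smiles(system_to_smiles(
        mol_system(atom_array(s$atoms$symbols[idx]),
                   s$B[idx, idx, drop = FALSE])))
    }, "")
    expect_true(up$smiles[r] %in% frags)
  }
})

test_that("census agrees with streaming dedup on toy arrays and the funnel is monotone", {
  a <- atom_array(c("C", "C", "N", "O"))
  census <- product_census(a)
  up <- unique_products(enumerate_matrices(a), min_heavy_atoms = 4)
  expect_setequal(census$smiles, up$smiles)
  n_mat <- as.numeric(count_matrices(a))
  n_orb <- count_orbit_matrices(a)
  expect_gte(n_mat, n_orb)
  expect_gte(n_orb, nrow(census))
})

test_that("census ring counts and sizes are internally consistent", {
  cen <- product_census(atom_array(c("C", "C", "C", "N", "O")))
  expect_true(all(cen$n_heavy_atoms >= 4))
  expect_true(all(cen$rings >= 0))
  expect_true(all(cen$min_bond_edit_distance >= 0))
  # ring counts recomputed from the parsed structures match
  idx <- seq_len(min(25L, nrow(cen)))
  expect_equal(ring_count(cen$smiles[idx]), cen$rings[idx])
})
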