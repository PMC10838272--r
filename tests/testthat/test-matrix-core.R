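test_that("element specs carry the neutral-atom bonding caps", {
  sp <- element_specs()
  expect_equal(sp$t[sp$symbol == "C"], 4L)
  expect_equal(sp$b[sp$symbol == "C"], 3L)
  expect_equal(sp$t[sp$symbol == "N"], 3L)
  expect_equal(sp$t[sp$symbol == "O"], 2L)
  expect_error(element_specs("Xx"), "no bonding parameters")
  expect_true(all(sp$b >= 1 & sp$b <= sp$t))
})

test_that("encoding the simple amine-acid pair reproduces the reference entries", {
  s <- simple_pair_system()
  expect_equal(s$B[2, 6], 1L)   # alpha-carbon to nitrogen single bond
  expect_equal(s$B[6, 2], 1L)
  expect_equal(s$B[5, 7], 2L)   # carbonyl double bond
  expect_equal(s$B[7, 5], 2L)
  expect_equal(s$B[5, 8], 1L)   # the acid OH
  expect_equal(sum(s$B[upper.tri(s$B)] > 0), 6L)
})

test_that("single-atom and aromatic encodings behave", {
  one <- smiles_to_system("C")
  expect_equal(dim(one$B), c(1L, 1L))
  expect_equal(one$B[1, 1], 0L)
  benz <- smiles_to_system("c1ccccc1")
  expect_true(all(sort(unique(benz$B[benz$B > 0])) == c(1L, 2L)))  # kekulized
  expect_true(all(rowSums(benz$B) == 3L))  # plus one implicit H each
  expect_equal(implicit_hydrogens(benz), rep(1L, 6))
})

test_that("charged atoms and unknown elements are rejected with clear messages", {
  expect_error(smiles_to_system("CC[NH3+]"), "charged")
  expect_error(smiles_to_system("CCS"), "no bonding parameters")
})

test_that("validate_matrix names each violation", {
  a <- atom_array(c("C", "C"))
  r <- validate_matrix(bondmat(2, list(c(1, 2, 5))), a)
  expect_false(r$valid)
  expect_true(any(grepl("cap", r$violations)))
  oo <- validate_matrix(bondmat(2, list(c(1, 2, 3))), atom_array(c("O", "O")))
  expect_false(oo$valid)
  # octet: a carbon with total order 5 through two bonds
  a3 <- atom_array(c("C", "C", "C"))
  r3 <- validate_matrix(bondmat(3, list(c(1, 2, 3), c(1, 3, 2))), a3)
  expect_false(r3$valid)
  expect_true(any(grepl("octet violation row 1", r3$violations)))
  expect_true(validate_matrix(simple_pair_system()$B, amine_acid_array())$valid)
  expect_false(validate_matrix(matrix(0L, 2, 3), a)$valid)
})

test_that("matrix decodes to molecules: amide, full fragmentation, round trips", {
  tm <- sm_templates()$sp3_sp3
  amide <- apply_transformation(tm, amide_transformation())
  expect_s3_class(amide, "mol_system")
  smi <- system_to_smiles(amide, canonical = TRUE)
  # the system also contains the expelled water oxygen
  expect_setequal(strsplit(smi, ".", fixed = TRUE)[[1]],
                  c(canonical_smiles("CCC(=O)NCC"), "O"))
  zero <- mol_system(atom_array(c("C", "N", "O")), matrix(0L, 3, 3))
  expect_equal(system_to_smiles(zero), "C.N.O")
})

test_that("matrix -> molecule -> matrix round trip holds up to degeneracy, exhaustively", {
  for (a in toy_arrays()[c("CO", "CCO", "CNO", "CCNO")]) {
    systems <- enumerate_matrices(a)
    for (s in systems) {
      smi <- system_to_smiles(s)
      back <- smiles_to_system(smi)
      expect_equal(sort(back$atoms$symbols), sort(s$atoms$symbols))
      # compare canonical forms under the identical-element group after
      # aligning atom order by element
      ord1 <- order(s$atoms$symbols)
      ord2 <- order(back$atoms$symbols)
      c1 <- canonical_under_group(
        mol_system(atom_array(s$atoms$symbols[ord1]),
                   s$B[ord1, ord1, drop = FALSE]))
      c2 <- canonical_under_group(
        mol_system(atom_array(back$atoms$symbols[ord2]),
                   back$B[ord2, ord2, drop = FALSE]))
      expect_equal(unname(c1), unname(c2))
    }
  }
})

test_that("no decoded product carries a formal charge", {
  a <- atom_array(c("C", "C", "N", "O"))
  smi <- vapply(enumerate_matrices(a), system_to_smiles, "")
  expect_false(any(grepl("\\+|\\-", smi)))
  can <- canonical_smiles(smi)
  expect_false(any(grepl("\\+|\\]\\-|\\-\\]", can[!is.na(can)])))
})

test_that("sanitization of valid matrices virtually always succeeds and failures are flagged", {
  a <- atom_array(c("C", "C", "C", "N", "O"))
  smi <- vapply(enumerate_matrices(a), system_to_smiles, "")
  can <- canonical_smiles(smi)
  expect_gte(mean(!is.na(can)), 0.99)
})
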