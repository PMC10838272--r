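test_that("descriptor panel reproduces the anchor values", {
  d <- compute_descriptors(c("CCC(=O)NCC", "c1ccccc1", "CC"))
  expect_true(all(d$ok))
  expect_equal(d$HBD[1], 1)          # the amide N-H
  expect_equal(d$HBD[2], 0)
  expect_equal(d$rings[2], 1L)
  expect_equal(d$ROTB[3], 0)
  expect_equal(d$FSP3[3], 1.0)
  expect_equal(d$MW[1], 101.15, tolerance = 1e-3)
  expect_true(all(d$QED > 0 & d$QED < 1))
  expect_true(all(d$HBD >= 0 & d$HBA >= 0 & d$ROTB >= 0))
})

test_that("unparsable SMILES yield error records without stopping the batch", {
  d <- compute_descriptors(c("CCO", "not_a_molecule((", "CCN"))
  expect_equal(d$ok, c(TRUE, FALSE, TRUE))
  expect_true(is.na(d$MW[2]))
})

test_that("descriptors are deterministic and additive over fragments for HBD/HBA", {
  d1 <- compute_descriptors("CCO.CCN")
  d2 <- compute_descriptors(c("CCO", "CCN"))
  expect_equal(d1$HBD, sum(d2$HBD))
  expect_equal(d1$HBA, sum(d2$HBA))
  expect_identical(compute_descriptors("CCC(=O)NCC"),
                   compute_descriptors("CCC(=O)NCC"))
})

test_that("FSP3 offers both denominators", {
  d <- compute_descriptors("CC=C")  # 1 sp3 carbon of 3 carbons, 3 heavy atoms
  expect_equal(d$FSP3, 1 / 3)
  expect_equal(d$FSP3_heavy, 1 / 3)
  d2 <- compute_descriptors("CCO")  # 2 sp3 carbons, 3 heavy atoms
  expect_equal(d2$FSP3, 1)
  expect_equal(d2$FSP3_heavy, 2 / 3)
})

test_that("shape coordinates hit the rod, sphere and disc limits", {
  npr <- compute_npr(c("CC#CC#CC", "C1C2CC3CC1CC(C2)C3", "c1ccccc1"))
  expect_true(all(npr$embed_status == "ok"))
  expect_lt(npr$NPR1[1], 0.1)            # rod
  expect_gt(npr$NPR2[1], 0.9)
  expect_gt(npr$NPR1[2], 0.9)            # adamantane, near-spherical
  expect_gt(npr$NPR2[2], 0.9)
  expect_equal(npr$NPR1[3], 0.5, tolerance = 0.1)  # flat disc
  expect_equal(npr$NPR2[3], npr$NPR1[3], tolerance = 0.1)
})

test_that("every successful embedding satisfies the PMI triangle constraints", {
  cen <- product_census(atom_array(c("C", "C", "C", "N", "O")))
  smi <- head(cen$smiles, 60)
  npr <- compute_npr(smi)
  ok <- npr$embed_status == "ok"
  expect_gt(mean(ok), 0.9)
  expect_true(all(npr$NPR1[ok] <= npr$NPR2[ok] + 1e-9))
  expect_true(all(npr$NPR2[ok] <= 1 + 1e-9))
  expect_true(all(npr$NPR1[ok] + npr$NPR2[ok] >= 1 - 1e-9))
})

test_that("NPR is deterministic given the seed", {
  a <- compute_npr(c("CCC(=O)NCC", "C1CCCCC1"), seed = 7L)
  b <- compute_npr(c("CCC(=O)NCC", "C1CCCCC1"), seed = 7L)
  expect_identical(a, b)
})

test_that("embedding failure is a status, not an exception", {
  npr <- compute_npr(c("CCO", "((bad"))
  expect_equal(npr$embed_status, c("ok", "failed"))
})

test_that("property deltas join by index and zero out at the reference", {
  subp <- data.frame(index = 1:3,
                     smiles = c("CCC(=O)NCC", "CCOC(=O)CC", "CCC(=O)NCC"))
  ctr <- data.frame(index = c(1:2, 4L),
                    smiles = c("CCC(=O)NCC", "CCOC(=O)CC", "CCN"))
  expect_message(out <- property_deltas(subp, ctr, reference_index = 1L),
                 "unpaired")
  expect_equal(nrow(out), 2L)
  expect_equal(out$delta_full_MW[out$index == 1], 0)
  expect_equal(out$delta_center_HBD[out$index == 1], 0)
  # HBA/HBD deltas agree between full molecule and center when both sides
  # apply the same transformation to the same polar atoms
  expect_equal(out$delta_full_HBD[out$index == 2],
               out$delta_center_HBD[out$index == 2])
})
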