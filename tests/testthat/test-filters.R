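test_that("funnel filter applies both thresholds and reports drops", {
  rec <- data.frame(
    smiles = c("a", "b", "c", "d"),
    rings = c(0L, 5L, 2L, 0L),
    min_bond_edit_distance = c(2L, 1L, 9L, 6L))
  out <- funnel_filter(rec, max_rings = 4, max_edits = 6)
  expect_equal(out$smiles, c("a", "d"))
  expect_equal(attr(out, "n_dropped_rings"), 1L)
  expect_equal(attr(out, "n_dropped_edits"), 1L)
  expect_error(funnel_filter(rec[, 1:2]), "required column")
})

test_that("funnel filter is idempotent, subset-producing and threshold-monotone", {
  cen <- product_census(atom_array(c("C", "C", "C", "N", "O")))
  f1 <- funnel_filter(cen)
  expect_true(all(f1$smiles %in% cen$smiles))
  f2 <- funnel_filter(f1)
  expect_equal(f1$smiles, f2$smiles)
  relaxed <- funnel_filter(cen, max_rings = 10, max_edits = 20)
  tightened <- funnel_filter(cen, max_rings = 1, max_edits = 3)
  expect_gte(nrow(relaxed), nrow(f1))
  expect_lte(nrow(tightened), nrow(f1))
})

test_that("strained-motif filter separates textbook cases", {
  r <- strained_motif_filter(c(
    "C1CC2CCC1C=C2",     # norbornene: alkene away from the bridgehead
    "C1=C2CCC(C2)CC1",   # bridgehead alkene (anti-Bredt)
    "C1=CCCCC1"          # cyclohexene
  ))
  expect_true(r$pass[1])
  expect_false(r$pass[2])
  expect_true(r$pass[3])
  expect_true(is.na(r$motif[1]))
  expect_match(r$motif[2], "anti-Bredt")
})

test_that("strained-motif config is read and editable", {
  pats <- strained_motif_patterns()
  expect_true(all(c("smarts", "label") %in% names(pats)))
  expect_gte(nrow(pats), 3L)
  custom <- data.frame(smarts = "[C;r3]", label = "any cyclopropane")
  r <- strained_motif_filter(c("C1CC1", "CCC"), patterns = custom)
  expect_equal(r$pass, c(FALSE, TRUE))
})

test_that("aromaticity preservation check covers kept, broken and vacuous cases", {
  benzamide <- "NC(=O)c1ccccc1"
  expect_true(aromaticity_preserved(benzamide, benzamide))
  # dearomatized: same connectivity, one ring bond saturated
  expect_false(aromaticity_preserved("c1ccccc1", "C1CC=CC=C1"))
  expect_true(aromaticity_preserved("CCCC", "CCCC"))
})

test_that("composition filter applies strict inequalities", {
  twelve <- paste(rep("C", 11), collapse = "")     # 11 C + N = 12 heavy
  thirteen <- paste(rep("C", 12), collapse = "")   # 12 C + N = 13 heavy
  kept <- composition_filter(c(paste0("N", twelve), paste0("N", thirteen),
                               "CCNCC", "CCON"),
                             max_heavy = 13, max_NO = 2)
  expect_true(paste0("N", twelve) %in% kept)        # 12 < 13, 1 N < 2
  expect_false(paste0("N", thirteen) %in% kept)     # 13 is not < 13
  expect_true("CCNCC" %in% kept)
  expect_false("CCON" %in% kept)                    # N + O = 2 is not < 2
})

test_that("ring counts follow the cyclomatic definition", {
  expect_equal(ring_count("c1ccccc1"), 1L)
  expect_equal(ring_count("CCC(=O)NCC"), 0L)
  expect_equal(ring_count("C1CC2CCC1C=C2"), 2L)        # bicyclic
  expect_equal(ring_count("C1C2CC3CC1CC(C2)C3"), 3L)   # adamantane skeleton
  expect_equal(ring_count(c("C1CC1", "CC")), c(1L, 0L))
})
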