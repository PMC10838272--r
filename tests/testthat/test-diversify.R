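test_that("template mapping on the simple pair anchors at the functional groups", {
  m <- map_template_atoms("NCC", "CCC(=O)O", "sp3_sp3")
  g <- attr(m, "graph")
  expect_equal(g$symbols[m[["N"]]], "N")
  expect_equal(g$symbols[m[["carboxyl"]]], "C")
  expect_equal(sort(g$symbols[m]), sort(c(rep("C", 5), "N", "O", "O")))
  # carbonyl oxygen at position 7, hydroxyl at 8
  expect_equal(g$B[m[["carboxyl"]], m[["O1"]]], 2L)
  expect_equal(g$B[m[["carboxyl"]], m[["O2"]]], 1L)
  expect_equal(g$B[m[["am_alpha"]], m[["N"]]], 1L)
})

test_that("hybridization mismatches are a pattern-not-found error", {
  expect_error(map_template_atoms("Nc1ccccc1", "CCC(=O)O", "sp3_sp3"),
               "pattern not found")
  # and the sp2 template accepts the aniline
  m <- map_template_atoms("Nc1ccccc1", "C=CC(=O)O", "sp2_sp2")
  expect_length(m, 8L)
})

test_that("multiple distinct matches are reported and the first used", {
  # two carboxylic acids on one substrate
  expect_warning(
    m <- map_template_atoms("NCC", "OC(=O)CCC(=O)O", "sp3_sp3"),
    "distinct template matches")
  expect_gte(length(attr(m, "matches")), 2L)
})

test_that("diversifying the simple pair reproduces the enumerated products", {
  a4 <- atom_array(c("C", "C", "N", "O"))
  # build a transformation library from enumerated 4-atom systems embedded at
  # template positions (2, 5, 6, 7), referenced to the sp3/sp3 template
  tm <- sm_templates()$sp3_sp3
  tri <- enumerate_matrices(a4, mode = "matrices")
  sel <- c(2L, 5L, 6L, 7L)
  lib <- lapply(seq_len(nrow(tri)), function(r) {
    B <- matrix(0L, 8, 8)
    B[sel, sel] <- rxnspace:::tri_to_full(as.integer(tri[r, ]), 4L)
    unname(B - tm$B)
  })
  dv <- diversify("NCC", "CCC(=O)O", lib, template = "sp3_sp3")
  expect_equal(nrow(dv), length(lib))
  # every library entry lands in exactly one status; all applications of a
  # valid enumerated system to the unsubstituted pair must succeed
  expect_true(all(dv$status == "ok"))
  # and the products agree with direct application to the template system
  direct <- canonical_smiles(vapply(lib, function(T) {
    system_to_smiles(mol_system(tm$atoms, tm$B + T))
  }, ""))
  expect_equal(sort(unique(dv$smiles)), sort(unique(direct)))
})

test_that("identity and amide transformations act as expected on substrates", {
  lib <- list(matrix(0L, 8, 8), amide_transformation())
  dv <- diversify("NCC", "CCC(=O)O", lib)
  expect_equal(dv$status, c("ok", "ok"))
  expect_equal(dv$smiles[1], canonical_smiles("NCC.CCC(=O)O"))
  expect_setequal(strsplit(dv$smiles[2], ".", fixed = TRUE)[[1]],
                  c(canonical_smiles("CCC(=O)NCC"), "O"))
})

test_that("substituted alpha carbons make some transformations octet-violating", {
  # a transformation that raises the amine alpha-carbon to four heavy bonds:
  # fine for ethylamine, impossible once the alpha carbon carries two methyls
  T <- matrix(0L, 8, 8)
  T[2, 3] <- T[3, 2] <- 1L
  T[2, 4] <- T[4, 2] <- 1L
  ok <- diversify("NCC", "CCC(=O)O", list(T))
  expect_equal(ok$status, "ok")
  # three equivalent beta methyls: several matches, first one used
  crowded <- suppressWarnings(diversify("NC(C)(C)C", "CCC(=O)O", list(T)))
  expect_equal(crowded$status, "octet")
})

test_that("rejection categories partition the library", {
  lib <- list(matrix(0L, 8, 8), amide_transformation(),
              -sm_templates()$sp3_sp3$B,
              {T <- matrix(0L, 8, 8); T[1, 2] <- T[2, 1] <- -1L; T},
              {T <- matrix(0L, 8, 8); T[7, 8] <- T[8, 7] <- 3L; T})
  dv <- diversify("NCC", "CCC(=O)O", lib)
  expect_equal(nrow(dv), length(lib))
  expect_false(any(is.na(dv$status)))
  tab <- table(dv$status)
  expect_equal(sum(tab), length(lib))
  expect_true("bond_cap" %in% names(tab))  # the O#O attempt
})

test_that("aromaticity retention filters sp2-substrate products", {
  # break the aniline ring: remove one aromatic bond at the alpha-beta pair
  T <- matrix(0L, 8, 8)
  T[1, 2] <- T[2, 1] <- -1L
  dv_keep <- diversify("Nc1ccccc1", "C=CC(=O)O", list(T),
                       template = "sp2_sp2", keep_aromatic = TRUE)
  expect_equal(dv_keep$status, "aromaticity_broken")
  dv_free <- diversify("Nc1ccccc1", "C=CC(=O)O", list(T),
                       template = "sp2_sp2", keep_aromatic = FALSE)
  expect_equal(dv_free$status, "ok")
})

test_that("substituent-loss predicate flags fragmenting transformations", {
  # cut the acid alpha-beta bond of butyric acid: the detached beta carbon
  # carries an unmapped methyl, i.e. a substituent is lost
  T <- matrix(0L, 8, 8)
  T[3, 4] <- T[4, 3] <- -1L
  dv <- diversify("NCC", "CCCC(=O)O", list(T), no_substituent_loss = TRUE)
  expect_equal(dv$status, "substituent_loss")
  dv2 <- diversify("NCC", "CCCC(=O)O", list(T), no_substituent_loss = FALSE)
  expect_equal(dv2$status, "ok")
})

test_that("reaction centers align one-to-one with surviving indices", {
  lib <- list(matrix(0L, 8, 8), amide_transformation(),
              {T <- matrix(0L, 8, 8); T[5, 7] <- T[7, 5] <- 1L; T})
  dv <- diversify("NCC", "CCC(=O)O", lib)
  surv <- dv$index[dv$status == "ok"]
  centers <- generate_reaction_centers(surv, lib)
  expect_length(centers, length(surv))
  expect_identical(centers, generate_reaction_centers(surv, lib))
  amide_center <- centers[surv == 2]
  expect_setequal(strsplit(amide_center, ".", fixed = TRUE)[[1]],
                  c(canonical_smiles("CCC(=O)NCC"), "O"))
})
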