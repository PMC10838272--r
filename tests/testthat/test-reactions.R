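test_that("the four templates are valid two-fragment systems", {
  tm <- sm_templates()
  expect_named(tm, c("sp3_sp3", "sp3_sp2", "sp2_sp3", "sp2_sp2"))
  for (nm in names(tm)) {
    s <- tm[[nm]]
    expect_true(validate_matrix(s$B, s$atoms)$valid)
    expect_equal(length(unique(system_components(s))), 2L)
  }
  expect_equal(tm$sp2_sp3$B[1, 2], 2L)  # sp2 amine: alpha=beta double bond
  expect_equal(tm$sp3_sp2$B[3, 4], 2L)  # sp2 acid
  expect_equal(tm$sp3_sp3$B[1, 2], 1L)
})

test_that("amide transformation edits exactly the reference bond pairs", {
  tm <- sm_templates()$sp3_sp3
  amide <- apply_transformation(tm, amide_transformation())
  T <- derive_transformation(amide, tm)
  expect_equal(T[6, 5], 1L)    # N6-C5 formed
  expect_equal(T[5, 8], -1L)   # C5-O8 broken
  expect_equal(sum(T != 0), 4L)  # two symmetric pairs, nothing else
  expect_equal(bond_edit_distance(T), 2L)
})

test_that("bond edit distances of the textbook reactions", {
  expect_equal(bond_edit_distance(diels_alder_example()), 6L)
  # direct C-N cross-coupling: one bond formed
  cn <- matrix(0L, 2, 2)
  cn[1, 2] <- cn[2, 1] <- 1L
  expect_equal(bond_edit_distance(cn), 1L)
  expect_equal(bond_edit_distance(matrix(0L, 8, 8)), 0L)
})

test_that("derive/apply are mutually inverse across sampled enumerated products", {
  a <- amine_acid_array()
  tm <- sm_templates()$sp3_sp3
  tri <- enumerate_matrices(atom_array(c("C", "C", "N", "O")), mode = "matrices")
  # embed the 4-atom systems into the 8-atom array on atoms (2, 5, 6, 7)
  sel <- c(2L, 5L, 6L, 7L)
  for (r in seq_len(min(100L, nrow(tri)))) {
    B <- matrix(0L, 8, 8)
    B[sel, sel] <- rxnspace:::tri_to_full(as.integer(tri[r, ]), 4L)
    p <- mol_system(a, B)
    T <- derive_transformation(p, tm)
    back <- apply_transformation(tm, T)
    expect_false(is_rejected(back))
    expect_equal(back$B, p$B)
  }
})

test_that("edit distance is a metric on systems sharing an atom array", {
  a <- atom_array(c("C", "C", "N", "O"))
  tri <- enumerate_matrices(a, mode = "matrices")
  set.seed(7)
  idx <- matrix(sample(nrow(tri), 3 * 60, replace = TRUE), ncol = 3)
  d <- function(r1, r2) sum(abs(tri[r1, ] - tri[r2, ]))
  for (r in seq_len(nrow(idx))) {
    x <- idx[r, 1]; y <- idx[r, 2]; z <- idx[r, 3]
    expect_equal(d(x, y), d(y, x))
    expect_equal(d(x, x), 0)
    if (x != y) expect_gt(d(x, y), 0)
    expect_lte(d(x, z), d(x, y) + d(y, z))
  }
})

test_that("edit distance is invariant under simultaneous atom reordering", {
  tm <- sm_templates()$sp3_sp3
  amide <- apply_transformation(tm, amide_transformation())
  p <- sample(8)
  d1 <- bond_edit_distance(derive_transformation(amide, tm))
  d2 <- bond_edit_distance(amide$B[p, p] - tm$B[p, p])
  expect_equal(d1, d2)
})

test_that("min_edit_distance over templates is a lower bound and zero on templates", {
  tm <- sm_templates()
  for (nm in names(tm)) {
    r <- min_edit_distance(tm[[nm]])
    expect_equal(r$distance, 0L)
    expect_equal(r$template, nm)
  }
  amide <- apply_transformation(tm$sp3_sp3, amide_transformation())
  r <- min_edit_distance(amide)
  expect_equal(r$distance, 2L)
  for (nm in names(tm)) {
    expect_lte(r$distance,
               bond_edit_distance(derive_transformation(amide, tm[[nm]])))
  }
})

test_that("product fragment distances: amide is 2 under both residual conventions", {
  amide <- amide_product_system()
  expect_equal(product_min_edit(amide, residual = "fragmented"), 2L)
  expect_equal(product_min_edit(amide, residual = "template"), 2L)
  # fragmented residual charges the broken template bonds of leftover atoms
  butane <- smiles_to_system("CCCC")
  expect_equal(product_min_edit(butane, residual = "template"), 3L)
  expect_equal(product_min_edit(butane, residual = "fragmented"), 6L)
  expect_gte(product_min_edit(butane, "fragmented"),
             product_min_edit(butane, "template"))
})

test_that("invalid transformations are rejections, not exceptions", {
  tm <- sm_templates()$sp3_sp3
  # drive a bond negative
  T <- matrix(0L, 8, 8)
  T[1, 3] <- T[3, 1] <- -1L
  expect_true(is_rejected(apply_transformation(tm, T)))
  # octet violation
  T2 <- matrix(0L, 8, 8)
  T2[1, 3] <- T2[3, 1] <- 3L
  T2[1, 4] <- T2[4, 1] <- 3L
  expect_true(is_rejected(apply_transformation(tm, T2)))
  # complete fragmentation is fine: -B gives the all-zero system
  frag <- apply_transformation(tm, -tm$B)
  expect_false(is_rejected(frag))
  expect_equal(system_to_smiles(frag), "C.C.C.C.C.N.O.O")
})
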