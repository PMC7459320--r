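test_that("3D embedding is deterministic and gives force-field geometries", {
  mm <- fx_mols()$mols[["methane"]]
  m1 <- embed_and_refine(mm, seed = 7)
  m2 <- embed_and_refine(mm, seed = 7)
  expect_identical(m1$coords, m2$coords)
  ch <- sqrt(rowSums((m1$coords[2:5, , drop = FALSE] -
                        matrix(m1$coords[1, ], 4, 3, byrow = TRUE))^2))
  expect_true(all(ch > 1.05 & ch < 1.15))
})

test_that("unparsable structures are reported with their id, never zero-filled", {
  r <- read_smiles(c("CCO", "C1CC"), c("ok", "broken"))
  expect_named(r$mols, "ok")
  expect_equal(r$rejects$id, "broken")
  empty <- structure(list(id = "empty", elements = character(0),
                          bonds = matrix(integer(0), ncol = 3),
                          charges = integer(0), coords = NULL,
                          lines = character(0), source = "smiles"),
                     class = "lan_mol")
  expect_error(embed_and_refine(empty), class = "lanbind_featurization_failure")
})

test_that("named descriptors match independent references", {
  mols <- fx_mols()$mols
  expect_equal(compute_descriptors(mols[["benz"]], "NumHAcceptors")[[1]], 0)
  expect_equal(compute_descriptors(mols[["water"]], "MolWt")[[1]], 18.02,
               tolerance = 1e-3)
  # Balaban J for ethanol's heavy-atom path graph C-C-O, by hand:
  # distance row sums s = (3, 2, 3); two edges; cyclomatic number 0
  # J = 2 * (1/sqrt(3*2) + 1/sqrt(2*3)) = 4/sqrt(6)
  expect_equal(compute_descriptors(mols[["eth"]], "BalabanJ")[[1]],
               4 / sqrt(6), tolerance = 1e-9)
})

test_that("PEOE charges agree with the OpenBabel gasteiger oracle", {
  # compared on C/H/O/Cl chemistry where the two implementations share atom
  # typing; nitrogen planarity conventions differ between toolkits
  for (smi in c("CCO", "CCOCC", "ClCCCl", "CC(C)O", "CC(C)=O")) {
    mol2 <- ChemmineOB::convertFormat(
      "SMI", "MOL2", paste0(smi, " m\n"),
      options = data.frame(names = c("h", "partialcharge"),
                           args = c("", "gasteiger")))
    lines <- strsplit(mol2, "\n")[[1]]
    a0 <- grep("@<TRIPOS>ATOM", lines) + 1L
    a1 <- grep("@<TRIPOS>BOND", lines) - 1L
    ref <- as.numeric(vapply(strsplit(trimws(lines[a0:a1]), "\\s+"),
                             function(p) p[length(p)], ""))
    mol <- read_smiles(smi, "m")$mols[[1]]
    expect_equal(unname(peoe_charges(mol)), ref, tolerance = 2e-3)
  }
})

test_that("descriptors are invariant to atom input order", {
  layout <- default_descriptor_names()
  a <- read_smiles("OC(=O)c1ccccc1O", "a")$mols[[1]]
  b <- read_smiles("c1ccc(O)c(c1)C(O)=O", "b")$mols[[1]]  # renumbered atoms
  da <- compute_descriptors(a, layout)
  db <- compute_descriptors(b, layout)
  expect_equal(unname(da), unname(db), tolerance = 1e-9)
})

test_that("pruning removes fragment counts, null columns and duplicates", {
  set.seed(1)
  m <- cbind(fr_Ar_COO = rpois(40, 1), fr_Ar_OH = rpois(40, 1),
             fr_COO2 = rpois(40, 1),
             good_a = rnorm(40), good_b = rnorm(40),
             all_zero = rep(0, 40), mostly_zero = c(9, rep(0, 39)))
  m <- cbind(m, dup_of_a = m[, "good_a"])
  keep <- prune_descriptor_set(m)  # mostly_zero: 39/40 = 0.975 > 0.95
  expect_false(any(startsWith(keep, "fr_")))
  expect_false("all_zero" %in% keep)
  expect_false("mostly_zero" %in% keep)
  # of the identical pair, exactly one survives (alphabetically first)
  expect_true("dup_of_a" %in% keep)
  expect_false("good_a" %in% keep)
  expect_true("good_b" %in% keep)
  expect_identical(keep, sort(keep))
  expect_error(prune_descriptor_set(matrix(numeric(0), 0, 0)),
               class = "lanbind_config_error")
  # a column that is zero for 50% of molecules survives the default threshold
  m2 <- cbind(half_zero = rep(c(0, 1), 10), good = rnorm(20))
  expect_true("half_zero" %in% prune_descriptor_set(m2))
})

test_that("the frozen layout has 83 names and assembles to 102 features", {
  layout <- default_descriptor_names()
  expect_length(layout, 83L)
  expect_true(all(layout %in% all_descriptor_names()))
  expect_length(feature_names(), 102L)

  desc <- compute_descriptors(fx_mols()$mols[["glycine"]], layout)
  fv <- assemble_features(desc, lookup_metal("Eu", 3), lookup_medium("NaClO4"),
                          298, 0.1)
  expect_length(fv, 102L)
  expect_identical(names(fv), feature_names())
  # purity
  expect_identical(fv, assemble_features(desc, lookup_metal("Eu", 3),
                                         lookup_medium("NaClO4"), 298, 0.1))
  # block slicing recovers the inputs exactly
  expect_equal(unname(fv[1:83]), unname(desc))
  expect_equal(unname(fv[84:97]), unname(lookup_metal("Eu", 3)$properties))
  expect_equal(unname(fv[98:100]), unname(lookup_medium("NaClO4")$properties))
  expect_equal(unname(fv[101:102]), c(298, 0.1))
  # layout guard
  expect_error(assemble_features(desc[-1], lookup_metal("Eu", 3),
                                 lookup_medium("NaClO4"), 298, 0.1),
               class = "lanbind_feature_layout_error")
})
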