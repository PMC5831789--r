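# SMILES parsing into heavy-atom molecular graphs

test_that("simple molecules parse with correct atoms, bonds and hydrogens", {
  g <- parse_smiles("CCO")
  expect_equal(g$atoms$element, c("C", "C", "O"))
  expect_equal(nrow(g$bonds), 2L)
  expect_true(all(g$bonds$order == "single"))
  expect_equal(g$atoms$implicit_h, c(3L, 2L, 1L))

  benz <- parse_smiles("c1ccccc1")
  expect_equal(nrow(benz$atoms), 6L)
  expect_true(all(benz$atoms$aromatic))
  expect_equal(nrow(benz$bonds), 6L)
  expect_true(all(benz$bonds$order == "aromatic"))
  expect_equal(benz$atoms$implicit_h, rep(1L, 6L))

  # chloro-cyclopropane: 3-ring plus substituent, hand-enumerated
  g3 <- parse_smiles("C1CC1Cl")
  expect_equal(nrow(g3$atoms), 4L)
  expect_equal(nrow(g3$bonds), 4L)
  expect_equal(sort(vapply(g3$adj, nrow, 0L)), c(1L, 2L, 2L, 3L))
})

test_that("the valence model assigns implicit hydrogens with charge adjustment", {
  expect_equal(implicit_hydrogens("O", 1), 1L)
  expect_equal(implicit_hydrogens("C", 4), 0L)
  expect_equal(implicit_hydrogens("N", 3, +1), 1L)
  expect_equal(implicit_hydrogens("N", 4, +1), 0L)
  expect_error(implicit_hydrogens("Xx", 1), class = "gpcr_descriptor_error")
})

test_that("bracket atoms carry charge and explicit hydrogens", {
  g <- parse_smiles("[NH+](C)(C)C")
  expect_equal(g$atoms$charge[1L], 1L)
  expect_equal(g$atoms$implicit_h[1L], 1L)
  # bracket atom without an H count has zero hydrogens
  ac <- parse_smiles("CC(=O)[O-]")
  expect_equal(ac$atoms$charge[4L], -1L)
  expect_equal(ac$atoms$implicit_h[4L], 0L)
  nh4 <- parse_smiles("[NH4+]")
  expect_equal(nh4$atoms$charge, 1L)
  expect_equal(nh4$atoms$implicit_h, 4L)
  expect_equal(parse_smiles("[N++]CC")$atoms$charge[1L], 2L)
  expect_error(parse_smiles("[Fe+2]"), class = "gpcr_parse_error")
})

test_that("explicit bond symbols and ring-closure variants are honored", {
  g <- parse_smiles("C=C")
  expect_equal(g$bonds$order, "double")
  expect_equal(g$atoms$implicit_h, c(2L, 2L))
  expect_equal(parse_smiles("C#N")$bonds$order, "triple")
  # %nn ring closures equal single-digit ones
  a <- parse_smiles("C1CCCCC1")
  b <- parse_smiles("C%12CCCCC%12")
  expect_equal(a$bonds, b$bonds)
  # explicit single bond between aromatic atoms is kept single
  bip <- parse_smiles("c1ccccc1-c1ccccc1")
  expect_equal(sum(bip$bonds$order == "single"), 1L)
  expect_equal(sum(bip$bonds$order == "aromatic"), 12L)
})

test_that("disconnected components share one graph", {
  g <- parse_smiles("CCO.O")
  expect_equal(nrow(g$atoms), 4L)
  expect_equal(nrow(g$bonds), 2L)
})

test_that("malformed SMILES raise parse errors naming the position", {
  expect_error(parse_smiles("C(C"), class = "gpcr_parse_error")
  expect_error(parse_smiles("C1CC"), regexp = "ring-closure",
               class = "gpcr_parse_error")
  expect_error(parse_smiles("CQ"), regexp = "position 2",
               class = "gpcr_parse_error")
  expect_error(parse_smiles(""), class = "gpcr_parse_error")
  expect_error(parse_smiles("C)C"), class = "gpcr_parse_error")
  expect_error(parse_smiles("C=.C"), class = "gpcr_parse_error")
  expect_error(parse_smiles("C=="), class = "gpcr_parse_error")
})

test_that("stereo markers and isotopes are discarded, or rejected in strict mode", {
  g <- parse_smiles("F/C=C/F")
  expect_equal(nrow(g$atoms), 4L)
  expect_equal(sum(g$bonds$order == "double"), 1L)
  expect_error(parse_smiles("F/C=C/F", strict = TRUE),
               class = "gpcr_unsupported_error")
  expect_equal(nrow(parse_smiles("[13CH4]")$atoms), 1L)
  expect_error(parse_smiles("[13CH4]", strict = TRUE),
               class = "gpcr_unsupported_error")
  expect_equal(parse_smiles("C[C@H](N)O")$atoms$element, c("C", "C", "N", "O"))
})

test_that("equivalent SMILES spellings give identical graph summaries", {
  pairs <- list(c("C1CCCCC1", "C2CCCCC2"),
                c("Cc1ccccc1", "c1ccc(C)cc1"),
                c("CC(C)(C)C", "CC(C)(C)C"),
                c("c1ccc2ccccc2c1", "c2ccc1ccccc1c2"))
  for (p in pairs) {
    a <- parse_smiles(p[1L]); b <- parse_smiles(p[2L])
    expect_equal(nrow(a$atoms), nrow(b$atoms))
    expect_equal(nrow(a$bonds), nrow(b$bonds))
    expect_equal(sort(vapply(a$adj, nrow, 0L)), sort(vapply(b$adj, nrow, 0L)))
    expect_equal(sort(a$atoms$element), sort(b$atoms$element))
  }
})

test_that("adjacency is symmetric and degrees sum to twice the bond count", {
  mols <- c("CCO", "c1ccccc1", "CC(=O)Oc1ccccc1C(=O)O", "C1CC1Cl",
            "c1ccc2ccccc2c1", "CC(C)(C)C", "O=C1CCCCC1", "CCO.O")
  for (sm in mols) {
    g <- parse_smiles(sm)
    for (k in seq_len(nrow(g$bonds))) {
      a <- g$bonds$a[k]; b <- g$bonds$b[k]
      expect_true(b %in% g$adj[[a]]$nbr)
      expect_true(a %in% g$adj[[b]]$nbr)
    }
    expect_equal(sum(vapply(g$adj, nrow, 0L)), 2L * nrow(g$bonds))
    # parsing is deterministic
    expect_identical(g[c("atoms", "bonds")], parse_smiles(sm)[c("atoms", "bonds")])
  }
})

test_that(".smi files read as SMILES/ID records with unique IDs", {
  path <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("# comment", "CCO eth01", "c1ccccc1\tbenz01", ""), path)
  df <- read_smi(path)
  expect_equal(df$ligand_id, c("eth01", "benz01"))
  expect_equal(df$smiles, c("CCO", "c1ccccc1"))
  writeLines(c("CCO x", "CCC x"), path)
  expect_error(read_smi(path), class = "gpcr_io_error")
  writeLines("CCO", path)
  expect_error(read_smi(path), class = "gpcr_io_error")
})
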