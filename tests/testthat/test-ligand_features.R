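# Hub/cycle detection, canonical encodings, physicochemical descriptors

test_that("hubs are atoms at or above the heavy-degree threshold", {
  neo <- parse_smiles("CC(C)(C)C")
  expect_equal(find_hubs(neo, 4L), 2L)          # the quaternary carbon
  expect_equal(find_hubs(parse_smiles("c1ccccc1")), integer(0))
  tol <- parse_smiles("Cc1ccccc1")
  expect_equal(find_hubs(tol, 3L), 2L)          # ipso carbon, degree 3
  expect_error(find_hubs(neo, 2L), class = "gpcr_config_error")
})

test_that("hub codes sort satellites by element then bond precedence", {
  neo <- parse_smiles("CC(C)(C)C")
  expect_equal(encode_hub(neo, 2L), "C-C-C-C-C")
  tol <- parse_smiles("Cc1ccccc1")
  expect_equal(encode_hub(tol, 2L), "C-C:C:C")
  ace <- parse_smiles("CC(=O)[O-]")
  expect_equal(encode_hub(ace, 2L), "C-C-O=O")
  expect_error(encode_hub(neo, 1L), class = "gpcr_argument_error")
  expect_error(encode_hub(neo, 99L), class = "gpcr_argument_error")
})

test_that("hub codes are invariant to the SMILES atom ordering", {
  variants <- c("CC(C)(C)C", "C(C)(C)(C)C")
  codes <- lapply(variants, function(sm) {
    g <- parse_smiles(sm)
    sort(vapply(find_hubs(g, 4L), function(h) encode_hub(g, h, 4L), ""))
  })
  expect_identical(codes[[1L]], codes[[2L]])
})

test_that("cycle detection returns a minimum cycle basis of circuit-rank size", {
  expect_equal(find_cycles(parse_smiles("CCCCCC")), list())
  benz <- parse_smiles("c1ccccc1")
  cyc <- find_cycles(benz)
  expect_length(cyc, 1L)
  expect_length(cyc[[1L]], 6L)
  # fused bicyclic: two six-rings, never the ten-atom envelope
  naph <- parse_smiles("c1ccc2ccccc2c1")
  rings <- find_cycles(naph)
  expect_length(rings, oracle_circuit_rank(naph))
  expect_equal(vapply(rings, length, 0L), c(6L, 6L))
  # brute-force enumeration confirms the six-rings are the smallest cycles
  all_cycles <- enumerate_simple_cycles(naph)
  expect_equal(sort(unique(vapply(all_cycles, length, 0L))), c(6L, 10L))
})

test_that("cycle counts equal the circuit rank on parsed fixtures", {
  mols <- c("CCO", "c1ccccc1", "C1CC1Cl", "c1ccc2ccccc2c1",
            "C1CC2CCCC2C1", "c1ccccc1-c1ccccc1", "CCO.O",
            "O=C1CCCCC1", "C1CC1C1CC1")
  for (sm in mols) {
    g <- parse_smiles(sm)
    expect_length(find_cycles(g), oracle_circuit_rank(g))
  }
})

test_that("cycle codes are canonical over rotations and directions", {
  benz <- parse_smiles("c1ccccc1")
  expect_equal(encode_cycle(benz, find_cycles(benz)[[1L]]), "C:C:C:C:C:C:")
  # cyclohexanone: the exocyclic =O stays out of the ring code
  keto <- parse_smiles("O=C1CCCCC1")
  expect_equal(encode_cycle(keto, find_cycles(keto)[[1L]]), "C-C-C-C-C-C-")
  # 2H-pyran: golden value from the brute-force 12-candidate oracle
  pyran <- parse_smiles("C1CC=CCO1")
  ring <- find_cycles(pyran)[[1L]]
  expect_equal(encode_cycle(pyran, ring), oracle_cycle_code(pyran, ring))
  # invariance under any rotation/reversal of the supplied ring
  for (shift in 1:5) {
    rot <- ring[c((shift + 1):6, 1:shift)[1:6]]
    expect_equal(encode_cycle(pyran, rot), encode_cycle(pyran, ring))
    expect_equal(encode_cycle(pyran, rev(rot)), encode_cycle(pyran, ring))
  }
  expect_error(encode_cycle(benz, c(1L, 2L)), class = "gpcr_argument_error")
  expect_error(encode_cycle(benz, c(1L, 2L, 4L)), class = "gpcr_argument_error")
})

test_that("cycle codes match the brute-force oracle on heteroaromatic rings", {
  mols <- c("c1ccncc1", "c1ccoc1", "C1CCNC1", "c1ccsc1", "C1=CC=CN1")
  for (sm in mols) {
    g <- parse_smiles(sm)
    for (ring in find_cycles(g))
      expect_equal(encode_cycle(g, ring), oracle_cycle_code(g, ring))
  }
})

test_that("physicochemical descriptors follow the additive models", {
  eth <- compute_fourchars(parse_smiles("CCO"))
  expect_equal(unname(eth["MW"]), 46.07, tolerance = 0.01)
  expect_equal(unname(eth[c("HBD", "HBA")]), c(1, 1))
  acid <- compute_fourchars(parse_smiles("O=C(O)C"))
  expect_equal(unname(acid[c("HBD", "HBA")]), c(1, 2))
  expect_identical(attr(eth, "xlogp_source"), "approximate")
  sup <- compute_fourchars(parse_smiles("CCO"),
                           supplied = c(MW = 46.07, XlogP = -0.14,
                                        HBD = 1, HBA = 1))
  expect_identical(attr(sup, "xlogp_source"), "supplied")
  expect_equal(unname(sup["XlogP"]), -0.14)
  expect_error(compute_fourchars(parse_smiles("CCO"), strict = TRUE),
               class = "gpcr_descriptor_error")
})

test_that("ligand vectors count vocabulary codes and append descriptors", {
  benz <- parse_smiles("c1ccccc1")
  fc <- compute_fourchars(benz)
  v <- ligand_vector(benz, character(0), "C:C:C:C:C:C:", fc)
  expect_length(v, 5L)
  expect_equal(unname(v["Cycle:C:C:C:C:C:C:"]), 1)
  hex <- parse_smiles("CCCCCC")
  vh <- ligand_vector(hex, "C-C-C-C", c("C:C:C:C:C:C:", "C-C-C-C-C-C-"),
                      compute_fourchars(hex))
  expect_equal(unname(vh[1:3]), c(0, 0, 0))
  expect_gt(unname(vh["4chars:MW"]), 0)
  # two symmetric rings count twice
  bip <- parse_smiles("c1ccccc1-c1ccccc1")
  vb <- ligand_vector(bip, character(0), "C:C:C:C:C:C:",
                      compute_fourchars(bip))
  expect_equal(unname(vb["Cycle:C:C:C:C:C:C:"]), 2)
  # out-of-vocabulary codes are dropped and reported
  pyr <- parse_smiles("c1ccncc1")
  vp <- ligand_vector(pyr, character(0), "C:C:C:C:C:C:",
                      compute_fourchars(pyr))
  expect_equal(attr(vp, "dropped_codes"), "C:C:C:C:C:N:")
  expect_error(ligand_vector(benz, c("a", "a"), character(0), fc),
               class = "gpcr_argument_error")
})

test_that("hub and cycle multisets are invariant across equivalent spellings", {
  pairs <- list(c("Cc1ccccc1", "c1ccc(C)cc1"),
                c("c1ccc2ccccc2c1", "c2ccc1ccccc1c2"),
                c("CC(C)(C)c1ccccc1", "c1ccccc1C(C)(C)C"),
                c("O=C1CCCCC1", "C1CCC(=O)CC1"))
  for (p in pairs) {
    a <- parse_smiles(p[1L]); b <- parse_smiles(p[2L])
    code_sets <- function(g) {
      hubs <- sort(vapply(find_hubs(g), function(h) encode_hub(g, h), ""))
      rings <- sort(vapply(find_cycles(g), function(cy) encode_cycle(g, cy), ""))
      list(hubs, rings)
    }
    expect_identical(code_sets(a), code_sets(b))
  }
})

test_that("an added disconnected benzene adds one cycle and preserves codes", {
  base <- c("CCO", "CC(C)(C)C", "c1ccncc1", "O=C1CCCCC1")
  for (sm in base) {
    g0 <- parse_smiles(sm)
    g1 <- parse_smiles(paste0(sm, ".c1ccccc1"))
    codes0 <- vapply(find_cycles(g0), function(cy) encode_cycle(g0, cy), "")
    codes1 <- vapply(find_cycles(g1), function(cy) encode_cycle(g1, cy), "")
    expect_identical(sort(codes1), sort(c(codes0, "C:C:C:C:C:C:")))
    hubs0 <- vapply(find_hubs(g0), function(h) encode_hub(g0, h), "")
    hubs1 <- vapply(find_hubs(g1), function(h) encode_hub(g1, h), "")
    expect_identical(sort(hubs0), sort(hubs1))
  }
})
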