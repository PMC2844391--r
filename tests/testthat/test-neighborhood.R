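test_that("sphere membership uses an inclusive 8 A boundary", {
  ps <- toyStructure(c("A", "A", "A"),
                     rbind(c(0, 0, 0), c(7.99, 0, 0), c(8.01, 0, 0)))
  nbh <- buildNeighborhood(ps, 1, radius = 8)
  expect_true(2L %in% nbh@memberIndex)
  expect_false(3L %in% nbh@memberIndex)
  expect_true(1L %in% nbh@memberIndex)  # target always a member
})

test_that("an isolated target keeps itself and zero counts", {
  ps <- toyStructure("A", c(0, 0, 0))
  nbh <- buildNeighborhood(ps, 1)
  expect_equal(nbh@memberIndex, 1L)
  expect_equal(waterCount(nbh), 0L)
  expect_equal(length(nbh@hetIndex), 0L)
  # the residue's own atoms are inside its sphere
  expect_gte(atomicDensity(nbh), 5L)
})

test_that("membership and counts match a brute-force all-pairs scan", {
  for (seed in c(21, 22)) {
    ps <- readPDB(generateStructure(nResidues = 50, seed = seed,
                                    backgroundSpread = 30)$pdbLines)
    rp <- representativePoints(ps)
    for (i in c(1, 10, 25, 50)) {
      nbh <- buildNeighborhood(ps, i, repPoints = rp)
      ora <- oracleNeighborhood(ps, i)
      expect_equal(nbh@memberIndex, ora$members)
      expect_equal(waterCount(nbh), ora$waterCount)
      expect_equal(nbh@hetIndex, ora$hets)
      expect_equal(atomicDensity(nbh), ora$atomCount)
    }
  }
})

test_that("enlarging the radius never decreases any count", {
  ps <- readPDB(generateStructure(nResidues = 40, seed = 5)$pdbLines)
  for (i in c(3, 17)) {
    prev <- buildNeighborhood(ps, i, radius = 4)
    for (r in c(6, 8, 12, 20)) {
      cur <- buildNeighborhood(ps, i, radius = r)
      expect_true(all(prev@memberIndex %in% cur@memberIndex))
      expect_gte(waterCount(cur), waterCount(prev))
      expect_gte(atomicDensity(cur), atomicDensity(prev))
      expect_gte(length(cur@hetIndex), length(prev@hetIndex))
      prev <- cur
    }
  }
})

test_that("membership is symmetric in the representative-point metric", {
  ps <- readPDB(generateStructure(nResidues = 40, seed = 9)$pdbLines)
  rp <- representativePoints(ps)
  nbhs <- lapply(seq_len(nResidues(ps)), buildNeighborhood,
                 structure = ps, repPoints = rp)
  for (a in seq_len(nResidues(ps))) {
    for (b in nbhs[[a]]@memberIndex) {
      expect_true(a %in% nbhs[[b]]@memberIndex)
    }
  }
})

test_that("physico-chemical triples are normalized group fractions", {
  # I, V, L are all in the high-hydrophobicity group
  ps <- toyStructure(c("I", "V", "L"),
                     rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0)))
  pc <- physchemDistribution(buildNeighborhood(ps, 1))
  expect_equal(unname(pc[c("hydrophobicity.low", "hydrophobicity.medium",
                           "hydrophobicity.high")]), c(0, 0, 1))

  # mixed neighborhood: fractions match a hand tally from the group table
  aa <- c("R", "K", "G", "A", "C", "W")
  ps2 <- toyStructure(aa, cbind(seq_along(aa), 0, 0))
  nbh2 <- buildNeighborhood(ps2, 3, radius = 50)
  pc2 <- physchemDistribution(nbh2)
  # hydrophobicity groups: low RKEDQN, medium GASTPHY, high CLVIMFW
  expect_equal(unname(pc2["hydrophobicity.low"]), 2 / 6)
  expect_equal(unname(pc2["hydrophobicity.medium"]), 2 / 6)
  expect_equal(unname(pc2["hydrophobicity.high"]), 2 / 6)
  # polarizability groups: low GASDT, medium CPNVEQIL, high KMHFRYW
  expect_equal(unname(pc2["polarizability.low"]), 2 / 6)
  expect_equal(unname(pc2["polarizability.medium"]), 1 / 6)
  expect_equal(unname(pc2["polarizability.high"]), 3 / 6)

  # every property triple sums to 1 on a random non-empty neighborhood
  ps3 <- readPDB(generateStructure(nResidues = 30, seed = 2)$pdbLines)
  pc3 <- physchemDistribution(buildNeighborhood(ps3, 4))
  sums <- tapply(pc3, sub("\\..*$", "", names(pc3)), sum)
  expect_equal(as.numeric(sums), rep(1, 4), tolerance = 1e-12)
})

test_that("amino-acid composition is a normalized frequency vector", {
  ps <- toyStructure(c("A", "A", "G", "G"),
                     rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)))
  comp <- aaComposition(buildNeighborhood(ps, 1))
  expect_equal(unname(comp["A"]), 0.5)
  expect_equal(unname(comp["G"]), 0.5)
  expect_equal(sum(comp), 1)

  ps2 <- readPDB(generateStructure(nResidues = 30, seed = 13)$pdbLines)
  nbh2 <- buildNeighborhood(ps2, 7, radius = 15)
  comp2 <- aaComposition(nbh2)
  aa <- ps2@residues$aa[nbh2@memberIndex]
  for (a in AA20) {
    expect_equal(unname(comp2[a]), sum(aa == a) / length(aa))
  }
})

test_that("charge counts follow the R/K/H positive, D/E negative rule", {
  ps <- toyStructure(c("R", "K", "D"),
                     rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0)))
  expect_equal(unname(chargeFeatures(buildNeighborhood(ps, 1))), c(2, 1, 3))

  psN <- toyStructure(c("A", "G", "S"),
                      rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0)))
  expect_equal(unname(chargeFeatures(buildNeighborhood(psN, 1))), c(0, 0, 0))

  ps2 <- readPDB(generateStructure(nResidues = 30, seed = 17)$pdbLines)
  nbh2 <- buildNeighborhood(ps2, 11, radius = 12)
  aa <- ps2@residues$aa[nbh2@memberIndex]
  cf <- chargeFeatures(nbh2)
  expect_equal(unname(cf["nPos"]), sum(aa %in% c("R", "K", "H")))
  expect_equal(unname(cf["nNeg"]), sum(aa %in% c("D", "E")))
  expect_equal(unname(cf["nCharged"]), unname(cf["nPos"] + cf["nNeg"]))
})

test_that("waters are counted within the sphere radius only", {
  ps <- toyStructure("A", c(0, 0, 0),
                     waters = rbind(c(3, 0, 0), c(0, 7, 0), c(9, 0, 0)))
  expect_equal(waterCount(buildNeighborhood(ps, 1)), 2L)
})

test_that("neighborhood statistics are rigid-motion invariant", {
  ps <- readPDB(generateStructure(nResidues = 35, seed = 19)$pdbLines)
  R <- withr::with_seed(19, randomRotation())
  ps2 <- transformStructure(ps, R, c(12, -7, 30))
  bz <- normalizedBfactor(ps)
  bz2 <- normalizedBfactor(ps2)
  for (i in c(2, 9, 20)) {
    a <- neighborhoodStats(buildNeighborhood(ps, i), bfactorZ = bz)
    b <- neighborhoodStats(buildNeighborhood(ps2, i), bfactorZ = bz2)
    expect_equal(a, b, tolerance = 1e-9)
  }
})

test_that("the target can be excluded from composition statistics", {
  ps <- toyStructure(c("A", "G"), rbind(c(0, 0, 0), c(2, 0, 0)))
  nbh <- buildNeighborhood(ps, 1)
  withTarget <- aaComposition(nbh, includeTarget = TRUE)
  without <- aaComposition(nbh, includeTarget = FALSE)
  expect_equal(unname(withTarget["A"]), 0.5)
  expect_equal(unname(without["A"]), 0)
  expect_equal(unname(without["G"]), 1)
})
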