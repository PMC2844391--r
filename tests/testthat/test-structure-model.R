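test_that("PDB parsing groups atoms into residues, waters and heterogens", {
  lines <- c(
    atomLine("ATOM", 1, "N", " ", "ALA", "A", 1, c(0, 1, 0)),
    atomLine("ATOM", 2, "CA", " ", "ALA", "A", 1, c(0, 0, 0)),
    atomLine("ATOM", 3, "CB", " ", "ALA", "A", 1, c(1, 1, 1)),
    atomLine("ATOM", 4, "CA", " ", "GLY", "A", 2, c(5, 5, 5)),
    atomLine("ATOM", 5, "CA", " ", "SER", "A", 3, c(9, 0, 0)),
    atomLine("ATOM", 6, "OG", " ", "SER", "A", 3, c(10, 0, 0)),
    atomLine("HETATM", 7, "O", " ", "HOH", "A", 101, c(3, 3, 3)),
    atomLine("HETATM", 8, "O", " ", "HOH", "A", 102, c(30, 3, 3)),
    atomLine("HETATM", 9, "ZN", " ", "ZN", "A", 201, c(1, 2, 3), el = "ZN"),
    "END")
  ps <- readPDB(lines, pdbId = "FIXT")
  expect_equal(nResidues(ps), 3L)
  expect_equal(residues(ps)$aa, c("A", "G", "S"))
  expect_equal(nrow(waterCoords(ps)), 2L)
  expect_equal(hetGroups(ps)$code, "ZN")
  # single-atom heterogen: centroid is the atom position
  expect_equal(as.numeric(hetGroups(ps)[1, c("cx", "cy", "cz")]), c(1, 2, 3))
})

test_that("only the first MODEL of a multi-model file is read", {
  model1 <- c(
    "MODEL        1",
    atomLine("ATOM", 1, "CA", " ", "GLY", "A", 1, c(0, 0, 0)),
    atomLine("ATOM", 2, "CA", " ", "GLY", "A", 2, c(4, 0, 0)),
    "ENDMDL")
  model2 <- c(
    "MODEL        2",
    atomLine("ATOM", 1, "CA", " ", "GLY", "A", 1, c(50, 0, 0)),
    atomLine("ATOM", 2, "CA", " ", "GLY", "A", 2, c(54, 0, 0)),
    atomLine("ATOM", 3, "CA", " ", "GLY", "A", 3, c(58, 0, 0)),
    "ENDMDL")
  ps <- readPDB(c(model1, model2, "END"))
  expect_equal(nResidues(ps), 2L)
  expect_equal(representativePoint(ps, 1), c(0, 0, 0))
})

test_that("malformed coordinates raise an error naming the line", {
  bad <- atomLine("ATOM", 2, "CA", " ", "GLY", "A", 2, c(1, 1, 1))
  substr(bad, 31, 38) <- "  xx.yyy"
  lines <- c(atomLine("ATOM", 1, "CA", " ", "GLY", "A", 1, c(0, 0, 0)),
             bad, "END")
  expect_error(readPDB(lines), "line 2")
})

test_that("altLoc conformers are pruned to the highest occupancy", {
  lines <- c(
    atomLine("ATOM", 1, "CA", " ", "ALA", "A", 1, c(0, 0, 0)),
    atomLine("ATOM", 2, "CB", "A", "ALA", "A", 1, c(1, 0, 0), occ = 0.4),
    atomLine("ATOM", 3, "CB", "B", "ALA", "A", 1, c(2, 0, 0), occ = 0.6),
    "END")
  ps <- readPDB(lines)
  cb <- ps@atoms[ps@atoms$elety == "CB", ]
  expect_equal(nrow(cb), 1L)
  expect_equal(cb$x, 2)  # the 0.6-occupancy conformer
  # ties keep the first conformer in file order
  lines2 <- c(
    atomLine("ATOM", 1, "CA", " ", "ALA", "A", 1, c(0, 0, 0)),
    atomLine("ATOM", 2, "CB", "A", "ALA", "A", 1, c(1, 0, 0), occ = 0.5),
    atomLine("ATOM", 3, "CB", "B", "ALA", "A", 1, c(2, 0, 0), occ = 0.5),
    "END")
  ps2 <- readPDB(lines2)
  expect_equal(ps2@atoms[ps2@atoms$elety == "CB", "x"], 1)
})

test_that("unknown residue codes become 'X' with a warning; MSE maps to M", {
  lines <- c(
    atomLine("ATOM", 1, "CA", " ", "ALA", "A", 1, c(0, 0, 0)),
    atomLine("ATOM", 2, "CA", " ", "QQZ", "A", 2, c(4, 0, 0)),
    atomLine("HETATM", 3, "CA", " ", "MSE", "A", 3, c(8, 0, 0)),
    atomLine("HETATM", 4, "SE", " ", "MSE", "A", 3, c(9, 0, 0), el = "SE"),
    "END")
  expect_warning(ps <- readPDB(lines), "QQZ")
  expect_equal(residues(ps)$aa, c("A", "X", "M"))
  expect_equal(nrow(hetGroups(ps)), 0L)  # MSE is a residue, not a heterogen
})

test_that("a structure without ATOM records is rejected", {
  expect_error(readPDB(c(
    atomLine("HETATM", 1, "ZN", " ", "ZN", "A", 1, c(0, 0, 0), el = "ZN"),
    "END")), "ATOM")
})

test_that("representative points follow the side-chain centroid rule", {
  ps <- toyStructure(c("G", "A"), rbind(c(5, 5, 5), c(1, 1, 1)))
  expect_equal(representativePoint(ps, 1), c(5, 5, 5))  # glycine -> CA
  expect_equal(representativePoint(ps, 2), c(1, 1, 1))  # single CB

  # mean of several side-chain atoms
  lines <- c(
    atomLine("ATOM", 1, "CA", " ", "SER", "A", 1, c(-3, 0, 0)),
    atomLine("ATOM", 2, "CB", " ", "SER", "A", 1, c(0, 0, 0)),
    atomLine("ATOM", 3, "OG", " ", "SER", "A", 1, c(2, 0, 0)),
    atomLine("ATOM", 4, "CG", " ", "SER", "A", 1, c(4, 0, 0)),
    "END")
  ps2 <- readPDB(lines)
  expect_equal(representativePoint(ps2, 1), c(2, 0, 0))

  # truncated non-glycine residue falls back to CA with a warning
  lines3 <- c(atomLine("ATOM", 1, "CA", " ", "ALA", "A", 1, c(7, 8, 9)),
              "END")
  ps3 <- readPDB(lines3)
  expect_warning(p <- representativePoint(ps3, 1), "CA")
  expect_equal(p, c(7, 8, 9))
})

test_that("representative points lie inside the residue bounding box", {
  ps <- readPDB(generateStructure(nResidues = 40, seed = 7)$pdbLines)
  rp <- representativePoints(ps)
  for (i in seq_len(nResidues(ps))) {
    a <- ps@atoms[ps@atoms$residueIndex == i, ]
    expect_true(all(rp[i, ] >= c(min(a$x), min(a$y), min(a$z)) - 1e-9))
    expect_true(all(rp[i, ] <= c(max(a$x), max(a$y), max(a$z)) + 1e-9))
  }
})

test_that("normalized B-factors are population z-scores of residue means", {
  pts <- rbind(c(0, 0, 0), c(10, 0, 0))
  ps <- toyStructure(c("A", "A"), pts, bfac = c(10, 30))
  expect_equal(normalizedBfactor(ps), c(-1, 1))

  psEq <- toyStructure(c("A", "A", "A"),
                       rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0)),
                       bfac = c(20, 20, 20))
  expect_equal(normalizedBfactor(psEq), c(0, 0, 0))

  ps3 <- toyStructure(c("A", "A", "A"),
                      rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0)),
                      bfac = c(10, 20, 30))
  means <- sapply(1:3, function(i) {
    a <- ps3@atoms[ps3@atoms$residueIndex == i, ]
    mean(a$b)
  })
  zOracle <- (means - mean(means)) / sqrt(mean((means - mean(means))^2))
  expect_equal(normalizedBfactor(ps3), zOracle)
})

test_that("z-scored B-factors have mean 0 and unit population variance", {
  ps <- readPDB(generateStructure(nResidues = 60, seed = 11)$pdbLines)
  z <- normalizedBfactor(ps)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(mean(z^2), 1, tolerance = 1e-12)
})

test_that("parsing conserves the total atom count", {
  fix <- generateStructure(nResidues = 30, seed = 3)
  ps <- readPDB(fix$pdbLines)
  nRecords <- sum(grepl("^(ATOM  |HETATM)", fix$pdbLines))
  parsed <- nrow(ps@atoms) + nrow(ps@hetAtoms) + nrow(ps@waters)
  expect_equal(parsed, nRecords)
})
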