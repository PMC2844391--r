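uniformRow <- rep(1 / 20, 20)

profileFor <- function(rows) {
  newProfile(do.call(rbind, rows), nObs = 10)
}

classRow <- function(class, mass = 0.8) {
  members <- switch(class,
    charged = c("H", "R", "K", "E", "D"),
    polar = c("Q", "T", "S", "N", "C", "Y", "W"),
    hydrophobic = c("G", "F", "L", "M", "A", "I", "P", "V"))
  p <- rep((1 - mass) / (20 - length(members)), 20)
  names(p) <- AA20
  p[members] <- mass / length(members)
  unname(p[AA20])
}

test_that("class conservation thresholds the class mass at 0.5", {
  p <- newProfile(matrix(c(0, 0, 0.6, 0.4, rep(0, 16)), 1,
                         dimnames = list(NULL, AA20)))  # D .6, E .4
  expect_true(classConserved(p, 1, "charged"))          # 1.0 > 0.5
  expect_equal(conservedClass(p, 1), "charged")

  uni <- newProfile(matrix(uniformRow, 1))
  expect_false(classConserved(uni, 1, "hydrophobic"))   # 8/20 = 0.4
  expect_false(classConserved(uni, 1, "charged"))       # 5/20 = 0.25
  expect_false(classConserved(uni, 1, "polar"))         # 7/20 = 0.35
  expect_true(is.na(conservedClass(uni, 1)))
})

test_that("shape extraction enumerates anchored segments and triangles", {
  # target + one conserved residue at 4.2 A -> one segment with edge bin 4
  ps <- toyStructure(c("A", "D"), rbind(c(0, 0, 0), c(4.2, 0, 0)))
  prof <- profileFor(list(uniformRow, classRow("charged")))
  ss <- extractShapes(buildNeighborhood(ps, 1), prof)
  expect_equal(unname(shapeCounts(ss)), 1L)
  expect_equal(names(shapeCounts(ss)), "S|Ch|4")

  # no conserved residues -> empty shape set
  ssEmpty <- extractShapes(buildNeighborhood(ps, 1),
                           profileFor(list(uniformRow, uniformRow)))
  expect_length(shapeCounts(ssEmpty), 0)

  # target + two conserved residues, all pairwise < 5 A:
  # two segments and one triangle
  ps3 <- toyStructure(c("A", "D", "L"),
                      rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0)))
  prof3 <- profileFor(list(uniformRow, classRow("charged"),
                           classRow("hydrophobic")))
  ss3 <- extractShapes(buildNeighborhood(ps3, 1), prof3)
  counts3 <- shapeCounts(ss3)
  expect_equal(sum(counts3), 3L)
  expect_equal(sum(startsWith(names(counts3), "S|")), 2L)
  expect_equal(sum(startsWith(names(counts3), "T|")), 1L)
})

test_that("connectivity prunes shapes with edges beyond 5 A", {
  ps <- toyStructure(c("A", "D", "E"),
                     rbind(c(0, 0, 0), c(4, 0, 0), c(0, 6, 0)))
  prof <- profileFor(list(uniformRow, classRow("charged"),
                          classRow("charged")))
  nbh <- buildNeighborhood(ps, 1)
  connected <- extractShapes(nbh, prof, connectedOnly = TRUE)
  loose <- extractShapes(nbh, prof, connectedOnly = FALSE)
  # residue 3 is 6 A from the target: its segment and the triangle survive
  # only without the connectivity requirement
  expect_equal(sum(shapeCounts(connected)), 1L)
  expect_equal(sum(shapeCounts(loose)), 3L)
})

test_that("congruent shapes share one canonical key", {
  # identical labeled geometry enumerated in a different file order must
  # canonicalize to the same shape keys
  ps1 <- toyStructure(c("A", "D", "L"),
                      rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0)))
  ps2 <- toyStructure(c("A", "L", "D"),
                      rbind(c(0, 0, 0), c(0, 4, 0), c(3, 0, 0)))
  profA <- profileFor(list(uniformRow, classRow("charged"),
                           classRow("hydrophobic")))
  profB <- profileFor(list(uniformRow, classRow("hydrophobic"),
                           classRow("charged")))
  sA <- extractShapes(buildNeighborhood(ps1, 1), profA,
                      connectedOnly = FALSE)
  sB <- extractShapes(buildNeighborhood(ps2, 1), profB,
                      connectedOnly = FALSE)
  cA <- shapeCounts(sA)
  cB <- shapeCounts(sB)
  expect_equal(cA[sort(names(cA))], cB[sort(names(cB))])
  expect_equal(shapeKernel(sA, sB), shapeKernel(sA, sA))
})

test_that("the kernel is a dot product over shared canonical shapes", {
  opts <- list(requireTargetVertex = TRUE, connectedOnly = TRUE,
               conservedOnly = TRUE, binWidth = 1, connectDist = 5,
               conservedThreshold = 0.5)
  mk <- function(counts) new("ShapeSet", counts = counts, options = opts)
  a <- mk(c("S|Ch|3" = 2L, "T|Ch:3|Hy:4|2" = 1L))
  b <- mk(c("S|Ch|3" = 3L, "S|Po|2" = 5L))
  expect_equal(shapeKernel(a, b), 6)
  expect_equal(shapeKernel(b, a), 6)                       # symmetry
  expect_equal(shapeKernel(mk(c("S|Hy|1" = 1L)), b), 0)    # disjoint
  # adding a shared shape never decreases the kernel
  a2 <- mk(c("S|Ch|3" = 2L, "T|Ch:3|Hy:4|2" = 1L, "S|Po|2" = 1L))
  expect_gte(shapeKernel(a2, b), shapeKernel(a, b))
  # option mismatch is an error
  optsOther <- opts; optsOther$binWidth <- 2
  expect_error(
    shapeKernel(a, new("ShapeSet", counts = c("S|Ch|3" = 1L),
                       options = optsOther)), "options")
})

test_that("Gram matrices are symmetric PSD and combine with a base kernel", {
  ens <- generateEnsemble(nProteins = 1, nResidues = 20, seed = 23)
  ps <- ens$structures[[1]]
  prof <- ens$profiles[[1]]
  rp <- representativePoints(ps)
  sets <- lapply(seq_len(nResidues(ps)), function(i)
    extractShapes(buildNeighborhood(ps, i, repPoints = rp), prof))
  K <- gramMatrix(sets)
  expect_equal(K, t(K))
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
             -1e-9)
  expect_true(all(diag(K) >= 0))
  # Gram equals the pairwise kernel oracle
  for (i in c(1, 5)) {
    for (j in c(2, 20)) {
      expect_equal(K[i, j], shapeKernel(sets[[i]], sets[[j]]))
    }
  }
  base <- diag(length(sets))
  expect_equal(gramMatrix(sets, base = base, lambda = 0), base)
  expect_equal(gramMatrix(sets, base = base, lambda = 2), base + 2 * K)
  expect_error(gramMatrix(sets, base = base, lambda = -1), "non-negative")
})

test_that("shape sets are rigid-motion invariant", {
  ens <- generateEnsemble(nProteins = 1, nResidues = 25, seed = 29)
  ps <- ens$structures[[1]]
  prof <- ens$profiles[[1]]
  R <- withr::with_seed(29, randomRotation())
  ps2 <- transformStructure(ps, R, c(-20, 4, 9))
  for (i in c(1, 8, 15)) {
    s1 <- extractShapes(buildNeighborhood(ps, i), prof)
    s2 <- extractShapes(buildNeighborhood(ps2, i), prof)
    expect_equal(shapeCounts(s1)[sort(names(shapeCounts(s1)))],
                 shapeCounts(s2)[sort(names(shapeCounts(s2)))])
  }
})

test_that("shape sets serialize and round-trip through the text format", {
  ens <- generateEnsemble(nProteins = 1, nResidues = 15, seed = 37)
  s <- extractShapes(buildNeighborhood(ens$structures[[1]], 2),
                     ens$profiles[[1]])
  f <- withr::local_tempfile(fileext = ".shapes")
  writeShapeSet(s, f)
  back <- readShapeSet(f)
  expect_equal(shapeCounts(back), shapeCounts(s))
  expect_equal(shapeKernel(back, s), shapeKernel(s, s))
})
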