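# Builders and independent brute-force oracles shared across the suite.
# Oracles deliberately use naive loops over the parsed atom tables so they
# stay independent of the package's vectorized implementations.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

atomLine <- function(record, serial, name, alt, resn, chain, resno, xyz,
                     occ = 1, b = 10, el = substr(name, 1, 1)) {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, alt, resn, chain, resno,
          xyz[1], xyz[2], xyz[3], occ, b, el)
}

aa3 <- function(a) bio3d::aa123(a)

# structure with one side-chain pseudo-atom per residue placed exactly at
# the requested representative point (CA for glycine), plus backbone
toyStructure <- function(aa, pts, hets = NULL, waters = NULL,
                         bfac = NULL, ssbond = NULL, chain = "A") {
  pts <- matrix(pts, ncol = 3)
  stopifnot(length(aa) == nrow(pts))
  if (is.null(bfac)) bfac <- rep(10, length(aa))
  lines <- character(0)
  serial <- 0L
  if (!is.null(ssbond)) {
    for (k in seq_len(nrow(ssbond))) {
      lines <- c(lines, sprintf(
        "SSBOND %3d CYS %s %4d    CYS %s %4d", k,
        chain, ssbond[k, 1], chain, ssbond[k, 2]))
    }
  }
  for (i in seq_along(aa)) {
    p <- pts[i, ]
    add <- function(name, xyz, el = substr(name, 1, 1)) {
      serial <<- serial + 1L
      lines <<- c(lines, atomLine("ATOM", serial, name, " ", aa3(aa[i]),
                                  chain, i, xyz, b = bfac[i], el = el))
    }
    if (aa[i] == "G") {
      add("CA", p)
    } else {
      add("CA", p + c(1.5, 0, 0))
    }
    add("N", p + c(2.2, 1.0, 0))
    add("C", p + c(2.2, -1.0, 0))
    add("O", p + c(3.3, -1.2, 0))
    if (aa[i] != "G") {
      if (aa[i] == "C") add("SG", p, el = "S") else add("CB", p)
    }
  }
  if (!is.null(hets)) {
    for (k in seq_len(nrow(hets))) {
      serial <- serial + 1L
      code <- hets$code[k]
      lines <- c(lines, atomLine("HETATM", serial, code, " ", code, chain,
                                 800L + k,
                                 c(hets$x[k], hets$y[k], hets$z[k]),
                                 el = substr(code, 1, 2)))
    }
  }
  if (!is.null(waters)) {
    waters <- matrix(waters, ncol = 3)
    for (k in seq_len(nrow(waters))) {
      serial <- serial + 1L
      lines <- c(lines, atomLine("HETATM", serial, "O", " ", "HOH", chain,
                                 850L + k, waters[k, ], el = "O"))
    }
  }
  readPDB(c(lines, "END"), pdbId = "TOYS")
}

randomRotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# rigid-body transform of every coordinate of a parsed structure
transformStructure <- function(ps, R, t = c(0, 0, 0)) {
  rot <- function(x, y, z) t(R %*% rbind(x, y, z) + t)
  a <- ps@atoms
  a[, c("x", "y", "z")] <- rot(a$x, a$y, a$z)
  ps@atoms <- a
  if (nrow(ps@hetAtoms)) {
    h <- ps@hetAtoms
    h[, c("x", "y", "z")] <- rot(h$x, h$y, h$z)
    ps@hetAtoms <- h
  }
  if (nrow(ps@hets)) {
    g <- ps@hets
    g[, c("cx", "cy", "cz")] <- rot(g$cx, g$cy, g$cz)
    ps@hets <- g
  }
  if (nrow(ps@waters))
    ps@waters <- unname(as.matrix(rot(ps@waters[, 1], ps@waters[, 2],
                                      ps@waters[, 3])))
  ps
}

# --- brute-force oracles ----------------------------------------------------

oracleRepPoint <- function(ps, i) {
  a <- ps@atoms[ps@atoms$residueIndex == i, ]
  if (ps@residues$aa[i] == "G")
    return(as.numeric(a[a$elety == "CA", c("x", "y", "z")]))
  side <- a[!(a$elety %in% c("N", "CA", "C", "O", "OXT")) &
              !(a$element %in% c("H", "D")), ]
  if (nrow(side) == 0)
    return(as.numeric(a[a$elety == "CA", c("x", "y", "z")][1, ]))
  c(mean(side$x), mean(side$y), mean(side$z))
}

oracleNeighborhood <- function(ps, i, radius = 8) {
  n <- nrow(ps@residues)
  cen <- oracleRepPoint(ps, i)
  members <- integer(0)
  for (jj in seq_len(n)) {
    p <- oracleRepPoint(ps, jj)
    if (sqrt(sum((p - cen)^2)) <= radius) members <- c(members, jj)
  }
  wc <- 0L
  if (nrow(ps@waters))
    for (k in seq_len(nrow(ps@waters)))
      if (sqrt(sum((ps@waters[k, ] - cen)^2)) <= radius) wc <- wc + 1L
  hets <- integer(0)
  if (nrow(ps@hets))
    for (k in seq_len(nrow(ps@hets)))
      if (sqrt(sum((as.numeric(ps@hets[k, c("cx", "cy", "cz")]) - cen)^2))
          <= radius) hets <- c(hets, k)
  ac <- 0L
  for (k in seq_len(nrow(ps@atoms))) {
    p <- as.numeric(ps@atoms[k, c("x", "y", "z")])
    if (sqrt(sum((p - cen)^2)) <= radius) ac <- ac + 1L
  }
  if (nrow(ps@hetAtoms))
    for (k in seq_len(nrow(ps@hetAtoms))) {
      p <- as.numeric(ps@hetAtoms[k, c("x", "y", "z")])
      if (sqrt(sum((p - cen)^2)) <= radius) ac <- ac + 1L
    }
  list(members = members, waterCount = wc, hets = hets, atomCount = ac)
}

oracleCofactorBond <- function(ps, i, threshold = 3) {
  ra <- ps@atoms[ps@atoms$residueIndex == i &
                   !(ps@atoms$element %in% c("H", "D")), ]
  ha <- ps@hetAtoms[!(ps@hetAtoms$element %in% c("H", "D")), , drop = FALSE]
  if (!nrow(ra) || !nrow(ha)) return(0)
  best <- Inf
  for (p in seq_len(nrow(ra)))
    for (q in seq_len(nrow(ha)))
      best <- min(best, sqrt((ra$x[p] - ha$x[q])^2 +
                             (ra$y[p] - ha$y[q])^2 +
                             (ra$z[p] - ha$z[q])^2))
  as.numeric(best <= threshold)
}

oracleDisulphide <- function(ps, i, threshold = 2.5) {
  if (ps@residues$aa[i] != "C") return(0)
  ss <- ps@ssbonds
  r <- ps@residues[i, ]
  if (nrow(ss) &&
      any((ss$chain1 == r$chain & ss$resno1 == r$resno) |
          (ss$chain2 == r$chain & ss$resno2 == r$resno))) return(1)
  sg <- ps@atoms[ps@atoms$residueIndex == i & ps@atoms$elety == "SG", ]
  if (!nrow(sg)) return(0)
  for (jj in setdiff(which(ps@residues$aa == "C"), i)) {
    o <- ps@atoms[ps@atoms$residueIndex == jj & ps@atoms$elety == "SG", ]
    if (nrow(o) && sqrt((o$x[1] - sg$x[1])^2 + (o$y[1] - sg$y[1])^2 +
                        (o$z[1] - sg$z[1])^2) <= threshold) return(1)
  }
  0
}

# overlapping-class fixture with protein grouping and ~1:50 imbalance;
# with j = 1 the SVM predicts almost nothing positive, so tuning must
# select an upweighted cost factor
imbalancedFixture <- function(nProteins = 10, perProtein = 102, seed = 5) {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(nProteins), function(p) {
      nPos <- 2
      nNeg <- perProtein - nPos
      data.frame(
        protein = sprintf("P%02d", p), chain = "A",
        number = seq_len(perProtein), insert = "",
        residue = "A",
        label = c(rep(1L, nPos), rep(-1L, nNeg)),
        sig1 = c(rnorm(nPos, 1.1), rnorm(nNeg, 0)),
        sig2 = c(rnorm(nPos, 0.8), rnorm(nNeg, 0)),
        noise = rnorm(perProtein),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

# random small structure used by the geometry-oracle sweeps
randomFixture <- function(seed, nRes = 25) {
  withr::with_seed(seed, {
    generateStructure(nResidues = nRes, nCatalytic = 3,
                      backgroundSpread = 25,
                      hetPlan = data.frame(
                        code = sample(c("ZN", "MG", "CL", "PO4", "NAD"), 3),
                        dist = runif(3, 2, 20), stringsAsFactors = FALSE),
                      nWatersNearSite = 4, nWatersFar = 4, seed = seed)
  })
}
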