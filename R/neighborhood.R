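#' Build the spherical structural neighborhood of a residue
#'
#' Collects the content of a sphere of radius \code{radius} centered on the
#' representative point of the target residue: member residues (by their
#' representative point; the target is always a member), water molecules
#' (by oxygen coordinate), heterogen groups (by centroid) and the count of
#' non-water atoms (polymer and heterogen atoms, each by its own
#' coordinate). Distances are Euclidean and the boundary is inclusive
#' (d <= radius).
#'
#' @param structure a \code{\linkS4class{ProteinStructure}}
#' @param target residue row index (see \code{\link{residueIndex}})
#' @param radius sphere radius in Angstrom (default 8, the maximum
#'   residue-water interaction distance)
#' @param repPoints optional precomputed matrix from
#'   \code{\link{representativePoints}} (avoids recomputation when building
#'   neighborhoods for many residues of one structure)
#' @return a \code{\linkS4class{StructuralNeighborhood}}
#' @examples
#' ps <- readPDB(generateStructure(nResidues = 30, seed = 1)$pdbLines)
#' nbh <- buildNeighborhood(ps, 1)
#' neighborhoodStats(nbh)
#' @export
buildNeighborhood <- function(structure, target, radius = 8,
                              repPoints = NULL) {
  stopifnot(is(structure, "ProteinStructure"))
  target <- as.integer(target)
  if (is.na(target) || target < 1L || target > nrow(structure@residues))
    stop("target residue not in structure")
  if (radius <= 0) stop("radius must be positive")
  if (is.null(repPoints)) repPoints <- representativePoints(structure)
  center <- repPoints[target, ]

  d <- sqrt(colSums((t(repPoints) - center)^2))
  memberIndex <- which(d <= radius)

  waterCount <- 0L
  if (nrow(structure@waters)) {
    dw <- sqrt(colSums((t(structure@waters) - center)^2))
    waterCount <- sum(dw <= radius)
  }

  hetIndex <- integer(0)
  if (nrow(structure@hets)) {
    hc <- as.matrix(structure@hets[, c("cx", "cy", "cz")])
    dh <- sqrt(colSums((t(hc) - center)^2))
    hetIndex <- which(dh <= radius)
  }

  pa <- structure@atoms
  da <- sqrt((pa$x - center[1])^2 + (pa$y - center[2])^2 +
             (pa$z - center[3])^2)
  atomCount <- sum(da <= radius)
  if (nrow(structure@hetAtoms)) {
    haa <- structure@hetAtoms
    dha <- sqrt((haa$x - center[1])^2 + (haa$y - center[2])^2 +
                (haa$z - center[3])^2)
    atomCount <- atomCount + sum(dha <= radius)
  }

  new("StructuralNeighborhood", structure = structure,
      targetIndex = target, radius = radius,
      memberIndex = as.integer(memberIndex),
      memberDist = as.numeric(d[memberIndex]),
      waterCount = as.integer(waterCount),
      hetIndex = as.integer(hetIndex),
      atomCount = as.integer(atomCount))
}

memberAA <- function(nbh, includeTarget = TRUE) {
  idx <- nbh@memberIndex
  if (!includeTarget) idx <- setdiff(idx, nbh@targetIndex)
  nbh@structure@residues$aa[idx]
}

.physchemTable <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      f <- system.file("extdata", "physchem_groups.csv", package = "catres",
                       mustWork = TRUE)
      cache <<- utils::read.csv(f, stringsAsFactors = FALSE)
    }
    cache
  }
})

#' Physico-chemical group tables
#'
#' The three-group (low/medium/high) amino-acid partitions for
#' hydrophobicity, polarity, polarizability and van der Waals volume used
#' by the neighborhood distribution features. Shipped as a plain-text CSV
#' (\code{extdata/physchem_groups.csv}) so the assignment is auditable and
#' swappable.
#'
#' @param table optional replacement data.frame with columns
#'   \code{property}, \code{group} (low/medium/high), \code{residues}
#'   (string of one-letter codes)
#' @return data.frame of the active group table
#' @export
physchemGroups <- function(table = NULL) {
  if (is.null(table)) return(.physchemTable())
  stopifnot(all(c("property", "group", "residues") %in% names(table)))
  table
}

#' Three-bin physico-chemical distributions of a neighborhood
#'
#' For each of hydrophobicity, polarity, polarizability and van der Waals
#' volume, the fraction of member residues falling in the low, medium and
#' high group. Each triple sums to 1 for a non-empty neighborhood; unknown
#' residues (aa = 'X') are excluded from numerator and denominator; an
#' empty neighborhood yields zeros.
#'
#' @param nbh a \code{\linkS4class{StructuralNeighborhood}}
#' @param includeTarget count the target residue itself (default TRUE)
#' @param table group table, see \code{\link{physchemGroups}}
#' @return named numeric vector of 12 fractions
#'   (\code{<property>.<low|medium|high>})
#' @export
physchemDistribution <- function(nbh, includeTarget = TRUE, table = NULL) {
  stopifnot(is(nbh, "StructuralNeighborhood"))
  tab <- physchemGroups(table)
  aa <- memberAA(nbh, includeTarget)
  aa <- aa[aa %in% AA_ALPHABET]
  props <- unique(tab$property)
  groups <- c("low", "medium", "high")
  out <- numeric(0)
  for (p in props) {
    sub <- tab[tab$property == p, ]
    v <- setNames(numeric(3), groups)
    if (length(aa)) {
      for (g in groups) {
        members <- strsplit(sub$residues[sub$group == g], "")[[1L]]
        v[g] <- sum(aa %in% members) / length(aa)
      }
    }
    out <- c(out, setNames(v, paste(p, groups, sep = ".")))
  }
  out
}

#' Amino-acid composition of a neighborhood
#'
#' Relative frequency of each of the 20 amino acids among member residues
#' (alphabetical one-letter order). Sums to 1 for a non-empty neighborhood;
#' all zeros when empty. Unknown residues (aa = 'X') are skipped.
#'
#' @inheritParams physchemDistribution
#' @return named numeric vector of 20 frequencies
#' @export
aaComposition <- function(nbh, includeTarget = TRUE) {
  stopifnot(is(nbh, "StructuralNeighborhood"))
  aa <- memberAA(nbh, includeTarget)
  aa <- aa[aa %in% AA_ALPHABET]
  out <- setNames(numeric(20), AA_ALPHABET)
  if (length(aa)) {
    tab <- table(factor(aa, levels = AA_ALPHABET))
    out[] <- as.numeric(tab) / length(aa)
  }
  out
}

#' Charge counts of a neighborhood
#'
#' Number of positively charged (R, K, H) and negatively charged (D, E)
#' member residues, and their sum.
#'
#' @inheritParams physchemDistribution
#' @return named numeric vector \code{c(nPos, nNeg, nCharged)}
#' @export
chargeFeatures <- function(nbh, includeTarget = TRUE) {
  stopifnot(is(nbh, "StructuralNeighborhood"))
  aa <- memberAA(nbh, includeTarget)
  nPos <- sum(aa %in% AA_POSITIVE)
  nNeg <- sum(aa %in% AA_NEGATIVE)
  c(nPos = nPos, nNeg = nNeg, nCharged = nPos + nNeg)
}

#' Water count of a neighborhood
#' @param nbh a \code{\linkS4class{StructuralNeighborhood}}
#' @return integer number of water molecules inside the sphere
#' @export
waterCount <- function(nbh) {
  stopifnot(is(nbh, "StructuralNeighborhood"))
  nbh@waterCount
}

#' Atomic density of a neighborhood
#'
#' Total number of non-water atoms (polymer plus heterogen) whose
#' coordinates lie inside the sphere. Waters are counted separately by
#' \code{\link{waterCount}}.
#'
#' @param nbh a \code{\linkS4class{StructuralNeighborhood}}
#' @return integer atom count
#' @export
atomicDensity <- function(nbh) {
  stopifnot(is(nbh, "StructuralNeighborhood"))
  nbh@atomCount
}

#' All neighborhood-statistics features of a residue
#'
#' Convenience wrapper returning the full statistics block: the 12
#' physico-chemical fractions, the 20 amino-acid frequencies, the 3 charge
#' counts, the water count, the atomic density and the normalized B-factor
#' of the target residue.
#'
#' @inheritParams physchemDistribution
#' @param bfactorZ optional precomputed vector from
#'   \code{\link{normalizedBfactor}}
#' @return named numeric vector of 38 features
#' @export
neighborhoodStats <- function(nbh, includeTarget = TRUE, table = NULL,
                              bfactorZ = NULL) {
  stopifnot(is(nbh, "StructuralNeighborhood"))
  if (is.null(bfactorZ)) bfactorZ <- normalizedBfactor(nbh@structure)
  c(physchemDistribution(nbh, includeTarget, table),
    setNames(aaComposition(nbh, includeTarget),
             paste0("aafreq.", AA_ALPHABET)),
    chargeFeatures(nbh, includeTarget),
    waterCount = as.numeric(waterCount(nbh)),
    atomicDensity = as.numeric(atomicDensity(nbh)),
    bfactorZ = as.numeric(bfactorZ[nbh@targetIndex]))
}
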