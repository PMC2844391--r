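randUnit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

randInBall <- function(radius) {
  randUnit() * radius * stats::runif(1)^(1 / 3)
}

pdbAtomLine <- function(record, serial, name, resn, chain, resno,
                        xyz, occ, b, element) {
  sprintf("%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, resn, chain, resno,
          xyz[1], xyz[2], xyz[3], occ, b, element)
}

#' Generate a synthetic enzyme structure with a planted active site
#'
#' Emits PDB text and a matching label table for a toy protein in which a
#' small cluster of catalytic residues (a planted active site) sits at the
#' origin, catalytic-class heterogens are placed at planned distances from
#' the site center, non-catalytic heterogens far away (> 15 Angstrom),
#' waters are scattered near the site and background residues are
#' dispersed through a larger volume. Residues carry a minimal atom set
#' (N, CA, C, O plus one side-chain pseudo-atom placed exactly at the
#' intended representative point; SG for cysteine, CB otherwise; glycine
#' is represented by its CA) -- sufficient for every feature the package
#' extracts, with no claim of rotamer realism. All randomness flows from
#' \code{seed}; the same seed yields byte-identical output.
#'
#' @param nResidues total residues (default 120)
#' @param nCatalytic planted catalytic residues (default 3); their mutual
#'   representative-point distances are at most \code{activeSiteRadius}
#' @param activeSiteRadius diameter bound of the planted site, Angstrom
#'   (default 6; must not exceed the 8 Angstrom neighborhood radius)
#' @param hetPlan data.frame \code{code}, \code{dist}: heterogens and the
#'   distance of their centroid from the site center. Codes classified
#'   non-catalytic must be planted beyond 15 Angstrom
#' @param nWatersNearSite waters within 5 Angstrom of the site center
#' @param nWatersFar waters beyond 15 Angstrom
#' @param backgroundSpread radius of the volume holding background
#'   residues, Angstrom
#' @param catalyticBfactor,backgroundBfactor mean residue B-factors; the
#'   planted site is made more rigid than the background
#' @param pdbId identifier written into the labels
#' @param chain chain identifier
#' @param seed RNG seed
#' @return list \code{pdbLines} (character vector) and \code{labels}
#'   (data.frame in the standard label schema)
#' @export
generateStructure <- function(nResidues = 120, nCatalytic = 3,
                              activeSiteRadius = 6,
                              hetPlan = data.frame(
                                code = c("ZN", "CL"), dist = c(4, 20),
                                stringsAsFactors = FALSE),
                              nWatersNearSite = 6, nWatersFar = 10,
                              backgroundSpread = 40,
                              catalyticBfactor = 12,
                              backgroundBfactor = 20,
                              pdbId = "S001", chain = "A", seed = 1) {
  stopifnot(nResidues >= nCatalytic, nCatalytic >= 0,
            activeSiteRadius > 0, activeSiteRadius <= 8)
  withSeed(seed, {
    nBg <- nResidues - nCatalytic
    # catalytic representative points inside a ball of diameter
    # activeSiteRadius -> pairwise distances bounded by construction
    catPts <- t(vapply(seq_len(nCatalytic),
                       function(i) randInBall(activeSiteRadius / 2),
                       numeric(3)))
    bgPts <- matrix(NA_real_, nBg, 3)
    placed <- catPts
    for (i in seq_len(nBg)) {
      ok <- FALSE
      for (attempt in seq_len(2000L)) {
        p <- randInBall(backgroundSpread)
        if (sqrt(sum(p^2)) < activeSiteRadius + 2) next
        if (nrow(placed) &&
            min(sqrt(colSums((t(placed) - p)^2))) < 1.5) next
        ok <- TRUE
        break
      }
      if (!ok)
        stop("infeasible geometry: too many residues for the given spread")
      bgPts[i, ] <- p
      placed <- rbind(placed, p)
    }

    catSlots <- sort(sample(nResidues, nCatalytic))
    aa <- character(nResidues)
    pts <- matrix(NA_real_, nResidues, 3)
    aa[catSlots] <- sample(c("D", "C", "H"), nCatalytic, replace = TRUE)
    aa[-catSlots] <- sample(AA_ALPHABET, nBg, replace = TRUE)
    pts[catSlots, ] <- catPts
    pts[-catSlots, ] <- bgPts

    lines <- character(0)
    serial <- 0L
    for (i in seq_len(nResidues)) {
      resn <- bio3d::aa123(aa[i])
      bBase <- if (i %in% catSlots)
        max(1, stats::rnorm(1, catalyticBfactor, 2))
      else max(1, stats::rnorm(1, backgroundBfactor, 5))
      p <- pts[i, ]
      atoms <- if (aa[i] == "G") {
        list(c(name = "N"), c(name = "CA"), c(name = "C"), c(name = "O"))
      } else {
        list(c(name = "N"), c(name = "CA"), c(name = "C"), c(name = "O"),
             c(name = if (aa[i] == "C") "SG" else "CB"))
      }
      offsets <- list(N = c(2.2, 1.0, 0), CA = c(1.53, 0, 0),
                      C = c(2.2, -1.0, 0), O = c(3.3, -1.2, 0))
      for (a in atoms) {
        nm <- a[["name"]]
        xyz <- if (nm %in% names(offsets)) {
          if (aa[i] == "G" && nm == "CA") p else p + offsets[[nm]]
        } else p
        el <- if (nm == "SG") "S" else substr(nm, 1, 1)
        serial <- serial + 1L
        lines <- c(lines, pdbAtomLine(
          "ATOM", serial, nm, resn, chain, i, xyz, 1,
          max(0.5, bBase + stats::rnorm(1, 0, 0.5)), el))
      }
    }

    hetResno <- 900L
    if (!is.null(hetPlan) && nrow(hetPlan)) {
      for (hi in seq_len(nrow(hetPlan))) {
        hetResno <- hetResno + 1L
        cen <- randUnit() * hetPlan$dist[hi]
        code <- toupper(hetPlan$code[hi])
        el <- substr(code, 1, 2)
        serial <- serial + 1L
        lines <- c(lines, pdbAtomLine(
          "HETATM", serial, code, code, chain, hetResno, cen, 1, 15, el))
      }
    }
    for (wi in seq_len(nWatersNearSite)) {
      hetResno <- hetResno + 1L
      serial <- serial + 1L
      lines <- c(lines, pdbAtomLine(
        "HETATM", serial, "O", "HOH", chain, hetResno,
        randUnit() * stats::runif(1, 1.5, 5), 1, 30, "O"))
    }
    for (wi in seq_len(nWatersFar)) {
      hetResno <- hetResno + 1L
      serial <- serial + 1L
      lines <- c(lines, pdbAtomLine(
        "HETATM", serial, "O", "HOH", chain, hetResno,
        randUnit() * stats::runif(1, 15, max(16, backgroundSpread)), 1,
        30, "O"))
    }
    lines <- c(lines, "END")

    labels <- data.frame(
      id = seq_len(nResidues),
      label = ifelse(seq_len(nResidues) %in% catSlots, 1L, -1L),
      protein_PDB_Id = pdbId, residue = aa, chain = chain,
      number = seq_len(nResidues), stringsAsFactors = FALSE)
    list(pdbLines = lines, labels = labels)
  })
}

#' Generate a conservation profile matching a planted structure
#'
#' Catalytic positions are strongly conserved: a mass of \code{strength}
#' sits on the true residue and the remainder is uniform over the other 19
#' amino acids, with a high effective observation count. Background
#' positions get noisy near-uniform distributions (symmetric Dirichlet
#' draws) with a low observation count, so their entropy is higher and
#' their reliability weight lower than at catalytic positions.
#'
#' @param structure a parsed \code{\linkS4class{ProteinStructure}}
#' @param labels labels data.frame identifying catalytic residues
#' @param strength conserved mass on the true residue, in (0, 1]
#' @param nObsCatalytic,nObsBackground effective observation counts
#' @param seed RNG seed
#' @return a \code{\linkS4class{ConservationProfile}}
#' @export
generateProfile <- function(structure, labels, strength = 0.9,
                            nObsCatalytic = 50, nObsBackground = 3,
                            seed = 1) {
  stopifnot(strength > 0, strength <= 1)
  withSeed(seed, {
    n <- nResidues(structure)
    key <- paste(structure@residues$chain, structure@residues$resno)
    lkey <- paste(labels$chain, labels$number)
    lab <- labels$label[match(key, lkey)]
    lab[is.na(lab)] <- -1L
    probs <- matrix(NA_real_, n, 20, dimnames = list(NULL, AA_ALPHABET))
    nObs <- numeric(n)
    for (i in seq_len(n)) {
      if (lab[i] == 1L && structure@residues$aa[i] %in% AA_ALPHABET) {
        p <- rep((1 - strength) / 19, 20)
        p[match(structure@residues$aa[i], AA_ALPHABET)] <- strength
        nObs[i] <- nObsCatalytic
      } else {
        g <- stats::rgamma(20, shape = 2)
        p <- g / sum(g)
        nObs[i] <- nObsBackground
      }
      probs[i, ] <- p
    }
    newProfile(probs, nObs)
  })
}

#' Generate an ensemble of planted synthetic proteins
#'
#' Convenience wrapper producing a parsed, labeled, profiled set of
#' synthetic structures ready for \code{\link{assembleFeatures}} and
#' \code{\link{crossValidate}}. Each protein gets its own deterministic
#' sub-seed derived from \code{seed}.
#'
#' @param nProteins number of proteins (default 20)
#' @param nResidues residues per protein (default 120)
#' @param nCatalytic catalytic residues per protein (default 3)
#' @param strength profile conservation strength at catalytic positions
#' @param seed master seed
#' @param ... further arguments passed to \code{\link{generateStructure}}
#' @return list \code{structures} (named list of
#'   \code{ProteinStructure}), \code{profiles} (named list of
#'   \code{ConservationProfile}), \code{labels} (combined data.frame)
#' @export
generateEnsemble <- function(nProteins = 20, nResidues = 120,
                             nCatalytic = 3, strength = 0.9, seed = 1,
                             ...) {
  structures <- list()
  profiles <- list()
  labels <- list()
  for (p in seq_len(nProteins)) {
    pid <- sprintf("S%03d", p)
    sub <- (seed * 997L + p * 13L) %% 2147483000L
    fix <- generateStructure(nResidues = nResidues,
                             nCatalytic = nCatalytic, pdbId = pid,
                             seed = sub, ...)
    ps <- readPDB(fix$pdbLines, pdbId = pid)
    structures[[pid]] <- ps
    profiles[[pid]] <- generateProfile(ps, fix$labels,
                                       strength = strength,
                                       seed = sub + 1L)
    labels[[pid]] <- fix$labels
  }
  lab <- do.call(rbind, labels)
  lab$id <- seq_len(nrow(lab))
  rownames(lab) <- NULL
  list(structures = structures, profiles = profiles, labels = lab)
}
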