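#' Parse a PDB file into a typed structure model
#'
#' Reads ATOM/HETATM/SSBOND/MODEL records of a PDB entry and returns a
#' \code{\linkS4class{ProteinStructure}}. Atom records are parsed with
#' \code{bio3d::read.pdb}; record-level policies are applied on top:
#' \itemize{
#'   \item only the first MODEL of a multi-model file is read;
#'   \item alternate locations are pruned to the highest-occupancy conformer
#'     (ties broken by file order);
#'   \item HETATM groups named HOH/WAT/DOD become water molecules
#'     (represented by their oxygen coordinate);
#'   \item all other HETATM groups become heterogen groups keyed by
#'     (code, chain, seq number), represented also by the centroid of their
#'     atoms;
#'   \item modified residues listed in \code{modres} (default MSE -> M) are
#'     treated as polymer residues; other unknown residue codes are kept
#'     with \code{aa = "X"} and a warning.
#' }
#'
#' @param input path to a PDB file, or a character vector of PDB lines.
#' @param pdbId identifier stored in the result; defaults to the file stem
#'   (or \code{"XXXX"} for in-memory input).
#' @param modres named character vector mapping 3-letter modified-residue
#'   codes to one-letter codes; such HETATM groups are treated as residues.
#' @return a \code{\linkS4class{ProteinStructure}}.
#' @examples
#' pdb <- generateStructure(nResidues = 20, seed = 1)
#' ps <- readPDB(pdb$pdbLines, pdbId = "S001")
#' nResidues(ps)
#' @export
readPDB <- function(input, pdbId = NULL, modres = c(MSE = "M")) {
  if (length(input) == 1L && !grepl("\n", input) && file.exists(input)) {
    lines <- readLines(input, warn = FALSE)
    if (is.null(pdbId))
      pdbId <- toupper(sub("\\.(pdb|ent)$", "", basename(input)))
  } else {
    lines <- as.character(unlist(strsplit(input, "\n", fixed = TRUE)))
    if (is.null(pdbId)) pdbId <- "XXXX"
  }

  # keep only the first model
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1L] - 1L)]

  isRec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(grepl("^ATOM  ", lines)))
    stop("no ATOM records found in PDB input")

  # validate coordinate fields before handing off to the reader
  recIdx <- which(isRec)
  for (fld in list(c(31L, 38L), c(39L, 46L), c(47L, 54L))) {
    v <- suppressWarnings(
      as.numeric(trimws(substr(lines[recIdx], fld[1L], fld[2L]))))
    if (anyNA(v))
      stop(sprintf("malformed coordinate field at line %d",
                   recIdx[which(is.na(v))[1L]]))
  }

  ssbonds <- parseSSBOND(lines)

  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  pdb <- bio3d::read.pdb(tmp, verbose = FALSE, rm.alt = FALSE)
  at <- pdb$atom
  at$chain[is.na(at$chain) | at$chain == ""] <- "A"
  at$insert[is.na(at$insert)] <- ""
  at$o[is.na(at$o)] <- 1
  at$b[is.na(at$b)] <- 0
  at$elesy[is.na(at$elesy) | at$elesy == ""] <-
    substr(trimws(at$elety[is.na(at$elesy) | at$elesy == ""]), 1L, 1L)
  if (any(at$b < 0))
    warning("negative B-factors present; kept as-is")

  # altLoc: keep the highest-occupancy conformer per atom, ties -> first
  akey <- paste(at$type, at$chain, at$resno, at$insert, at$resid, at$elety)
  ord <- order(akey, -at$o, seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(akey[ord]), , drop = FALSE]
  at <- at[order(as.integer(rownames(at))), , drop = FALSE]

  resid <- toupper(at$resid)
  isWater <- resid %in% WATER_CODES
  isModres <- at$type == "HETATM" & resid %in% names(modres)
  isPolymer <- (at$type == "ATOM" | isModres) & !isWater

  # waters: one oxygen coordinate per water group
  waters <- matrix(numeric(0), ncol = 3,
                   dimnames = list(NULL, c("x", "y", "z")))
  if (any(isWater)) {
    w <- at[isWater, , drop = FALSE]
    wkey <- paste(w$chain, w$resno, w$insert)
    keep <- !logical(nrow(w))
    isO <- toupper(w$elesy) == "O"
    # prefer the oxygen atom of each water group
    first <- tapply(seq_len(nrow(w)),
                    factor(wkey, levels = unique(wkey)),
                    function(i) if (any(isO[i])) i[isO[i]][1L] else i[1L])
    w <- w[as.integer(first), , drop = FALSE]
    waters <- cbind(x = w$x, y = w$y, z = w$z)
  }

  # polymer residues in order of first appearance
  pa <- at[isPolymer, , drop = FALSE]
  pkey <- paste(pa$chain, pa$resno, pa$insert)
  pfac <- factor(pkey, levels = unique(pkey))
  pa$residueIndex <- as.integer(pfac)
  firstRow <- match(levels(pfac), pkey)
  res3 <- toupper(pa$resid[firstRow])
  aa <- suppressWarnings(bio3d::aa321(res3))  # we warn once ourselves below
  aa[res3 %in% names(modres)] <- unname(modres[res3[res3 %in% names(modres)]])
  unknown <- is.na(aa) | !(aa %in% AA_ALPHABET)
  if (any(unknown)) {
    warning(sprintf("unknown residue code(s) %s kept with aa = 'X'",
                    paste(unique(res3[unknown]), collapse = ", ")))
    aa[unknown] <- "X"
  }
  residues <- data.frame(
    chain = pa$chain[firstRow], resno = pa$resno[firstRow],
    insert = pa$insert[firstRow], aa = aa,
    nAtoms = as.integer(table(pfac)),
    stringsAsFactors = FALSE)
  atoms <- data.frame(
    residueIndex = pa$residueIndex, chain = pa$chain, resno = pa$resno,
    insert = pa$insert, resid = toupper(pa$resid),
    aa = aa[pa$residueIndex],
    elety = trimws(pa$elety), element = toupper(trimws(pa$elesy)),
    x = pa$x, y = pa$y, z = pa$z, b = pa$b, o = pa$o,
    stringsAsFactors = FALSE)

  # heterogen groups (non-water, non-polymer HETATM)
  ha <- at[!isPolymer & !isWater, , drop = FALSE]
  hets <- data.frame(code = character(), chain = character(),
                     resno = integer(), cx = numeric(), cy = numeric(),
                     cz = numeric(), nAtoms = integer(),
                     stringsAsFactors = FALSE)
  hetAtoms <- data.frame(hetIndex = integer(), code = character(),
                         elety = character(), element = character(),
                         x = numeric(), y = numeric(), z = numeric(),
                         b = numeric(), stringsAsFactors = FALSE)
  if (nrow(ha)) {
    hkey <- paste(toupper(ha$resid), ha$chain, ha$resno, ha$insert)
    hfac <- factor(hkey, levels = unique(hkey))
    hFirst <- match(levels(hfac), hkey)
    hets <- data.frame(
      code = toupper(ha$resid[hFirst]), chain = ha$chain[hFirst],
      resno = ha$resno[hFirst],
      cx = as.numeric(tapply(ha$x, hfac, mean)),
      cy = as.numeric(tapply(ha$y, hfac, mean)),
      cz = as.numeric(tapply(ha$z, hfac, mean)),
      nAtoms = as.integer(table(hfac)), stringsAsFactors = FALSE)
    hetAtoms <- data.frame(
      hetIndex = as.integer(hfac), code = toupper(ha$resid),
      elety = trimws(ha$elety), element = toupper(trimws(ha$elesy)),
      x = ha$x, y = ha$y, z = ha$z, b = ha$b, stringsAsFactors = FALSE)
  }

  new("ProteinStructure", pdbId = pdbId, atoms = atoms,
      residues = residues, hetAtoms = hetAtoms, hets = hets,
      waters = waters, ssbonds = ssbonds)
}

parseSSBOND <- function(lines) {
  ss <- lines[grepl("^SSBOND", lines)]
  if (!length(ss))
    return(data.frame(chain1 = character(), resno1 = integer(),
                      icode1 = character(), chain2 = character(),
                      resno2 = integer(), icode2 = character(),
                      stringsAsFactors = FALSE))
  ss <- formatC(ss, width = 36, flag = "-")
  data.frame(
    chain1 = trimws(substr(ss, 16L, 16L)),
    resno1 = as.integer(trimws(substr(ss, 18L, 21L))),
    icode1 = trimws(substr(ss, 22L, 22L)),
    chain2 = trimws(substr(ss, 30L, 30L)),
    resno2 = as.integer(trimws(substr(ss, 32L, 35L))),
    icode2 = trimws(substr(ss, 36L, 36L)),
    stringsAsFactors = FALSE)
}

#' Row index of a residue by key
#'
#' @param structure a \code{ProteinStructure}
#' @param chain chain identifier
#' @param resno author residue number
#' @param insert insertion code (default none)
#' @return integer index into \code{residues(structure)}, or NA if absent
#' @export
residueIndex <- function(structure, chain, resno, insert = "") {
  r <- structure@residues
  idx <- which(r$chain == chain & r$resno == resno & r$insert == insert)
  if (length(idx)) idx[1L] else NA_integer_
}

#' Representative point of a residue
#'
#' The centroid of the side-chain heavy atoms (all atoms except the
#' backbone N, CA, C, O, OXT and hydrogens/deuteriums). Glycine, which has
#' no side chain, is represented by its C-alpha atom. A non-glycine residue
#' with no side-chain heavy atoms (e.g. truncated to backbone) falls back
#' to C-alpha with a warning.
#'
#' @param structure a \code{ProteinStructure}
#' @param index residue row index
#' @return numeric length-3 coordinate (Angstrom)
#' @export
representativePoint <- function(structure, index) {
  a <- structure@atoms
  rows <- a[a$residueIndex == index, , drop = FALSE]
  if (!nrow(rows)) stop("residue index not found in structure")
  aa <- structure@residues$aa[index]
  heavy <- !(rows$element %in% c("H", "D"))
  side <- heavy & !(rows$elety %in% BACKBONE_ATOMS)
  if (aa != "G" && any(side)) {
    return(c(mean(rows$x[side]), mean(rows$y[side]), mean(rows$z[side])))
  }
  ca <- which(rows$elety == "CA")
  if (!length(ca)) {
    if (aa != "G")
      stop("residue has neither side-chain heavy atoms nor CA")
    stop("glycine residue without CA atom")
  }
  if (aa != "G")
    warning(sprintf("residue %s %s%d has no side-chain heavy atoms; using CA",
                    aa, structure@residues$chain[index],
                    structure@residues$resno[index]))
  c(rows$x[ca[1L]], rows$y[ca[1L]], rows$z[ca[1L]])
}

#' Representative points of all residues
#'
#' @param structure a \code{ProteinStructure}
#' @return n x 3 numeric matrix, rows aligned with \code{residues(structure)}
#' @export
representativePoints <- function(structure) {
  n <- nrow(structure@residues)
  out <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  for (i in seq_len(n)) out[i, ] <- representativePoint(structure, i)
  out
}

#' Normalized residue B-factor
#'
#' Mean atomic B-factor per residue, z-scored (population standard
#' deviation) against the distribution of per-residue mean B-factors of the
#' whole structure. When all residues share the same mean B-factor the
#' z-scores are all 0.
#'
#' @param structure a \code{ProteinStructure}
#' @param index optional residue index; when given, returns that residue's
#'   value only
#' @return numeric vector over residues (or a single value)
#' @export
normalizedBfactor <- function(structure, index = NULL) {
  a <- structure@atoms
  means <- as.numeric(tapply(a$b, a$residueIndex, mean))
  mu <- mean(means)
  sdev <- sqrt(mean((means - mu)^2))
  z <- if (sdev > 0) (means - mu) / sdev else rep(0, length(means))
  if (is.null(index)) z else z[index]
}
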