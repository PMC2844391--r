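#' @title S4 containers
#' @name catres-classes
#' @description S4 classes holding parsed structures, spherical
#'   neighborhoods, conservation profiles and shape multisets.
NULL

#' Parsed protein structure
#'
#' Typed model of a PDB entry: polymer residues with their atoms, water
#' molecules, heterogen groups (non-water HETATM groups) and disulphide
#' (SSBOND) records. Only the first model of multi-model files is kept and
#' alternate locations are pruned to the highest-occupancy conformer.
#'
#' @slot pdbId four-character identifier (or file stem).
#' @slot atoms data.frame of polymer atoms: \code{residueIndex}, \code{chain},
#'   \code{resno}, \code{insert}, \code{resid}, \code{aa}, \code{elety},
#'   \code{element}, \code{x}, \code{y}, \code{z}, \code{b}, \code{o}.
#' @slot residues data.frame, one row per residue: \code{chain},
#'   \code{resno}, \code{insert}, \code{aa}, \code{nAtoms}.
#' @slot hetAtoms data.frame of heterogen atoms with a \code{hetIndex} key.
#' @slot hets data.frame, one row per heterogen group: \code{code},
#'   \code{chain}, \code{resno}, centroid \code{cx}, \code{cy}, \code{cz},
#'   \code{nAtoms}.
#' @slot waters numeric matrix (n x 3) of water oxygen coordinates.
#' @slot ssbonds data.frame of SSBOND partners (\code{chain1},
#'   \code{resno1}, \code{icode1}, \code{chain2}, \code{resno2},
#'   \code{icode2}).
#'
#' @seealso \code{\link{readPDB}}
#' @exportClass ProteinStructure
setClass("ProteinStructure",
  representation(
    pdbId = "character",
    atoms = "data.frame",
    residues = "data.frame",
    hetAtoms = "data.frame",
    hets = "data.frame",
    waters = "matrix",
    ssbonds = "data.frame"
  )
)

setValidity("ProteinStructure", function(object) {
  msg <- character()
  if (nrow(object@residues) < 1L)
    msg <- c(msg, "structure must contain at least one residue")
  key <- paste(object@residues$chain, object@residues$resno,
               object@residues$insert)
  if (anyDuplicated(key))
    msg <- c(msg, "residue keys (chain, resno, insert) must be unique")
  if (nrow(object@residues) > 0 &&
      !all(object@residues$aa %in% c(AA_ALPHABET, "X")))
    msg <- c(msg, "residue aa codes must be standard one-letter codes or 'X'")
  if (ncol(object@waters) != 3L)
    msg <- c(msg, "waters must be an n x 3 coordinate matrix")
  if (nrow(object@hets) > 0 &&
      any(toupper(object@hets$code) %in% WATER_CODES))
    msg <- c(msg, "water is never a heterogen group")
  if (length(msg)) msg else TRUE
})

#' Spherical structural neighborhood of a residue
#'
#' Content of a sphere of fixed radius centered on the representative point
#' (side-chain centroid; C-alpha for glycine) of a target residue: member
#' residues whose representative point falls within the radius (target
#' included), water oxygens within the radius, heterogen groups whose
#' centroid falls within the radius, and the count of non-water atoms inside
#' the sphere. Boundary is inclusive.
#'
#' @slot structure the parent \code{ProteinStructure}.
#' @slot targetIndex row index of the target residue in the parent.
#' @slot radius sphere radius, Angstrom.
#' @slot memberIndex residue indices inside the sphere (includes target).
#' @slot memberDist distances of member representative points to the target.
#' @slot waterCount number of water oxygens inside the sphere.
#' @slot hetIndex heterogen group indices whose centroid is inside.
#' @slot atomCount number of non-water atoms (polymer + heterogen) inside.
#'
#' @seealso \code{\link{buildNeighborhood}}, \code{\link{neighborhoodStats}}
#' @exportClass StructuralNeighborhood
setClass("StructuralNeighborhood",
  representation(
    structure = "ProteinStructure",
    targetIndex = "integer",
    radius = "numeric",
    memberIndex = "integer",
    memberDist = "numeric",
    waterCount = "integer",
    hetIndex = "integer",
    atomCount = "integer"
  )
)

setValidity("StructuralNeighborhood", function(object) {
  msg <- character()
  if (length(object@radius) != 1L || object@radius <= 0)
    msg <- c(msg, "radius must be a single positive value")
  if (!(object@targetIndex %in% object@memberIndex))
    msg <- c(msg, "target residue must be a member of its own neighborhood")
  if (object@waterCount < 0L || object@atomCount < 0L)
    msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Per-position conservation profile
#'
#' A 20-way amino-acid distribution per sequence position, as produced by a
#' PSI-Blast search, plus the effective number of observed sequences used for
#' the pseudocount reliability weight. Columns follow the alphabetical
#' one-letter ordering \code{A C D E F G H I K L M N P Q R S T V W Y}.
#'
#' @slot probs numeric matrix (L x 20); rows sum to 1.
#' @slot nObs effective observation count per position (NA when the source
#'   format does not carry it; the reliability weight is then 0).
#'
#' @seealso \code{\link{readProfile}}, \code{\link{profileEntropy}},
#'   \code{\link{profileWeight}}
#' @exportClass ConservationProfile
setClass("ConservationProfile",
  representation(probs = "matrix", nObs = "numeric")
)

setValidity("ConservationProfile", function(object) {
  msg <- character()
  if (ncol(object@probs) != 20L)
    msg <- c(msg, "probs must have 20 columns")
  if (nrow(object@probs) != length(object@nObs))
    msg <- c(msg, "nObs must have one entry per position")
  if (nrow(object@probs) > 0) {
    if (any(object@probs < -1e-12))
      msg <- c(msg, "profile probabilities must be non-negative")
    s <- rowSums(object@probs)
    if (any(abs(s - 1) > 1e-9))
      msg <- c(msg, "profile rows must sum to 1")
  }
  if (length(msg)) msg else TRUE
})

#' Multiset of canonical labeled shapes
#'
#' Canonicalized segments and triangles extracted from a residue
#' neighborhood, with occurrence counts, for the 3D decomposition kernel.
#' Two sets are comparable only when extracted under identical options
#' (recorded in \code{options}).
#'
#' @slot counts named integer vector; names are canonical shape keys.
#' @slot options named list of the extraction options used.
#'
#' @seealso \code{\link{extractShapes}}, \code{\link{shapeKernel}}
#' @exportClass ShapeSet
setClass("ShapeSet",
  representation(counts = "integer", options = "list")
)

setValidity("ShapeSet", function(object) {
  if (length(object@counts) && any(object@counts < 1L))
    "shape counts must be >= 1" else TRUE
})

#' @describeIn ProteinStructure compact display
#' @param object a \code{ProteinStructure}
#' @export
setMethod("show", "ProteinStructure", function(object) {
  cat(sprintf(
    "ProteinStructure '%s': %d residues, %d waters, %d heterogens, %d SSBOND\n",
    object@pdbId, nrow(object@residues), nrow(object@waters),
    nrow(object@hets), nrow(object@ssbonds)))
})

#' @describeIn StructuralNeighborhood compact display
#' @param object a \code{StructuralNeighborhood}
#' @export
setMethod("show", "StructuralNeighborhood", function(object) {
  tr <- object@structure@residues[object@targetIndex, ]
  cat(sprintf(
    "StructuralNeighborhood of %s %s%d (r = %.1f A): %d residues, %d waters, %d hets, %d atoms\n",
    tr$aa, tr$chain, tr$resno, object@radius,
    length(object@memberIndex), object@waterCount,
    length(object@hetIndex), object@atomCount))
})

#' @describeIn ConservationProfile compact display
#' @param object a \code{ConservationProfile}
#' @export
setMethod("show", "ConservationProfile", function(object) {
  cat(sprintf("ConservationProfile: %d positions\n", nrow(object@probs)))
})

#' @describeIn ShapeSet compact display
#' @param object a \code{ShapeSet}
#' @export
setMethod("show", "ShapeSet", function(object) {
  cat(sprintf("ShapeSet: %d distinct shapes, %d total\n",
              length(object@counts), sum(object@counts)))
})

#' Number of residues of a structure
#' @param x a \code{ProteinStructure}
#' @return integer residue count
#' @export
nResidues <- function(x) {
  stopifnot(is(x, "ProteinStructure"))
  nrow(x@residues)
}

#' Residue table of a structure
#' @param x a \code{ProteinStructure}
#' @return data.frame with one row per residue (chain, resno, insert, aa,
#'   nAtoms)
#' @export
residues <- function(x) {
  stopifnot(is(x, "ProteinStructure"))
  x@residues
}

#' Heterogen group table of a structure
#' @param x a \code{ProteinStructure}
#' @return data.frame with one row per heterogen group (code, chain, resno,
#'   centroid, nAtoms)
#' @export
hetGroups <- function(x) {
  stopifnot(is(x, "ProteinStructure"))
  x@hets
}

#' Water oxygen coordinates of a structure
#' @param x a \code{ProteinStructure}
#' @return n x 3 numeric matrix
#' @export
waterCoords <- function(x) {
  stopifnot(is(x, "ProteinStructure"))
  x@waters
}

#' Profile length (number of positions)
#' @param x a \code{ConservationProfile}
#' @return integer
#' @export
profileLength <- function(x) {
  stopifnot(is(x, "ConservationProfile"))
  nrow(x@probs)
}

#' Profile probability matrix
#' @param x a \code{ConservationProfile}
#' @return L x 20 matrix, columns in alphabetical one-letter order
#' @export
profileProbs <- function(x) {
  stopifnot(is(x, "ConservationProfile"))
  x@probs
}

#' Shape counts of a ShapeSet
#' @param x a \code{ShapeSet}
#' @return named integer vector of canonical shape counts
#' @export
shapeCounts <- function(x) {
  stopifnot(is(x, "ShapeSet"))
  x@counts
}
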