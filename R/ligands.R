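.hetClassTable <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      f <- system.file("extdata", "heterogen_classes.csv",
                       package = "catres", mustWork = TRUE)
      cache <<- utils::read.csv(f, stringsAsFactors = FALSE)
    }
    cache
  }
})

HET_CLASSES <- c("catalytic", "non_catalytic", "uncertain")

#' Heterogen class table
#'
#' Classification of PDB heterogen codes into catalytic, non-catalytic and
#' uncertain groups, derived from their literature roles and from the
#' distribution of their centroid distances to annotated catalytic
#' residues. Shipped as an editable CSV
#' (\code{extdata/heterogen_classes.csv}; 63 catalytic, 11 non-catalytic,
#' 7 uncertain codes).
#'
#' @param table optional replacement data.frame with columns \code{code},
#'   \code{class}
#' @return data.frame of the active table
#' @export
heterogenClassTable <- function(table = NULL) {
  if (is.null(table)) return(.hetClassTable())
  stopifnot(all(c("code", "class") %in% names(table)),
            all(table$class %in% HET_CLASSES))
  table
}

#' Classify a heterogen code
#'
#' Table lookup of the catalytic propensity class of a non-water heterogen
#' code. Codes absent from the table fall back to a configurable default
#' class (uncertain, the neutral choice, by default).
#'
#' @param code 3-letter PDB heterogen code
#' @param table see \code{\link{heterogenClassTable}}
#' @param default class for unlisted codes
#' @return one of "catalytic", "non_catalytic", "uncertain"
#' @examples
#' classifyHeterogen("ZN")   # catalytic
#' classifyHeterogen("CL")   # non_catalytic
#' classifyHeterogen("PO4")  # uncertain
#' @export
classifyHeterogen <- function(code, table = NULL,
                              default = c("uncertain", "catalytic",
                                          "non_catalytic")) {
  default <- match.arg(default)
  code <- toupper(code)
  if (code %in% WATER_CODES)
    stop("water is not a heterogen")
  tab <- heterogenClassTable(table)
  hit <- match(code, toupper(tab$code))
  if (is.na(hit)) default else tab$class[hit]
}

#' Heterogen-class counts in a neighborhood
#'
#' Number of potentially catalytic, non-catalytic and uncertain heterogen
#' groups whose centroid lies inside the sphere.
#'
#' @param nbh a \code{\linkS4class{StructuralNeighborhood}}
#' @param table see \code{\link{heterogenClassTable}}
#' @param default class for unlisted codes
#' @return named numeric vector \code{c(hetCatalytic, hetNonCatalytic,
#'   hetUncertain)}
#' @export
heterogenCounts <- function(nbh, table = NULL, default = "uncertain") {
  stopifnot(is(nbh, "StructuralNeighborhood"))
  out <- c(hetCatalytic = 0, hetNonCatalytic = 0, hetUncertain = 0)
  if (length(nbh@hetIndex)) {
    codes <- nbh@structure@hets$code[nbh@hetIndex]
    cls <- vapply(codes, classifyHeterogen, character(1),
                  table = table, default = default)
    out["hetCatalytic"] <- sum(cls == "catalytic")
    out["hetNonCatalytic"] <- sum(cls == "non_catalytic")
    out["hetUncertain"] <- sum(cls == "uncertain")
  }
  out
}

#' Disulphide-bonded cysteine flag
#'
#' 1 iff the residue is a cysteine and either appears in an SSBOND record
#' or has its SG atom within \code{threshold} Angstrom (default 2.5; a
#' canonical S-S bond is about 2.05) of another cysteine's SG. Cysteines
#' lacking an SG atom return 0 with a warning.
#'
#' @param structure a \code{\linkS4class{ProteinStructure}}
#' @param index residue row index
#' @param threshold SG-SG distance threshold, Angstrom
#' @return 0 or 1
#' @export
disulphideFlag <- function(structure, index, threshold = 2.5) {
  stopifnot(is(structure, "ProteinStructure"))
  r <- structure@residues[index, ]
  if (r$aa != "C") return(0)
  ss <- structure@ssbonds
  if (nrow(ss)) {
    hit <- (ss$chain1 == r$chain & ss$resno1 == r$resno &
              ss$icode1 == r$insert) |
           (ss$chain2 == r$chain & ss$resno2 == r$resno &
              ss$icode2 == r$insert)
    if (any(hit)) return(1)
  }
  a <- structure@atoms
  sg <- a[a$residueIndex == index & a$elety == "SG", , drop = FALSE]
  if (!nrow(sg)) {
    warning(sprintf("cysteine %s%d has no SG atom; disulphide flag 0",
                    r$chain, r$resno))
    return(0)
  }
  cysIdx <- setdiff(which(structure@residues$aa == "C"), index)
  other <- a[a$residueIndex %in% cysIdx & a$elety == "SG", , drop = FALSE]
  if (!nrow(other)) return(0)
  d <- sqrt((other$x - sg$x[1])^2 + (other$y - sg$y[1])^2 +
            (other$z - sg$z[1])^2)
  as.numeric(any(d <= threshold))
}

#' Cofactor bond flag
#'
#' 1 iff the minimum heavy-atom distance between any atom of the residue
#' and any heterogen atom is at most \code{threshold} Angstrom (default 3,
#' the bond-detection threshold).
#'
#' @param structure a \code{\linkS4class{ProteinStructure}}
#' @param index residue row index
#' @param threshold bond distance threshold, Angstrom
#' @return 0 or 1
#' @export
cofactorBondFlag <- function(structure, index, threshold = 3) {
  stopifnot(is(structure, "ProteinStructure"))
  ha <- structure@hetAtoms
  if (!nrow(ha)) return(0)
  a <- structure@atoms
  ra <- a[a$residueIndex == index & !(a$element %in% c("H", "D")), ,
          drop = FALSE]
  ha <- ha[!(ha$element %in% c("H", "D")), , drop = FALSE]
  if (!nrow(ra) || !nrow(ha)) return(0)
  for (i in seq_len(nrow(ra))) {
    d2 <- (ha$x - ra$x[i])^2 + (ha$y - ra$y[i])^2 + (ha$z - ra$z[i])^2
    if (any(d2 <= threshold^2)) return(1)
  }
  0
}

#' Heterogen-to-catalytic-residue distance histogram
#'
#' Distances from the centroid of every occurrence of a heterogen code to
#' the representative point of every catalytic residue of the same
#' structure, binned at \code{binWidth}. Used to assess whether a heterogen
#' tends to sit near catalytic sites (distance peak below ~15 Angstrom) or
#' far from them.
#'
#' @param structures list of \code{ProteinStructure}
#' @param labels labels data.frame (see \code{\link{readLabels}}); rows with
#'   \code{label == 1} mark catalytic residues
#' @param hetCode 3-letter heterogen code to analyze
#' @param binWidth histogram bin width, Angstrom (default 2)
#' @return data.frame with \code{from}, \code{to}, \code{count} (empty when
#'   the code or catalytic residues are absent); bins are [from, to)
#' @export
hetDistanceHistogram <- function(structures, labels, hetCode, binWidth = 2) {
  hetCode <- toupper(hetCode)
  dists <- numeric(0)
  for (ps in structures) {
    hets <- ps@hets
    hit <- which(hets$code == hetCode)
    if (!length(hit)) next
    lab <- labels[labels$protein_PDB_Id == ps@pdbId & labels$label == 1, ,
                  drop = FALSE]
    if (!nrow(lab)) next
    idx <- mapply(residueIndex, chain = lab$chain, resno = lab$number,
                  MoreArgs = list(structure = ps))
    idx <- idx[!is.na(idx)]
    if (!length(idx)) next
    rp <- representativePoints(ps)
    for (h in hit) {
      cen <- as.numeric(hets[h, c("cx", "cy", "cz")])
      dists <- c(dists,
                 sqrt(colSums((t(rp[idx, , drop = FALSE]) - cen)^2)))
    }
  }
  if (!length(dists))
    return(data.frame(from = numeric(0), to = numeric(0),
                      count = integer(0)))
  breaks <- seq(0, (floor(max(dists) / binWidth) + 1) * binWidth,
                by = binWidth)
  counts <- tabulate(findInterval(dists, breaks), nbins = length(breaks) - 1)
  data.frame(from = breaks[-length(breaks)], to = breaks[-1L],
             count = as.integer(counts))
}
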