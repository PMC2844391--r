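SHAPE_CLASS_ABBR <- c(charged = "Ch", hydrophobic = "Hy", polar = "Po")

#' Is a residue class conserved at a profile position?
#'
#' A class (charged, hydrophobic or polar, using the same partition as
#' \code{\link{encodeAaClass}}) is conserved at a position when the sum of
#' the profile entries of the amino acids belonging to it exceeds 0.5.
#'
#' @param profile a \code{\linkS4class{ConservationProfile}}
#' @param position position index
#' @param class "charged", "hydrophobic" or "polar"
#' @param threshold conservation threshold on the class mass (default 0.5)
#' @return logical
#' @export
classConserved <- function(profile, position, class, threshold = 0.5) {
  stopifnot(is(profile, "ConservationProfile"),
            class %in% AA_CLASSES)
  members <- names(AA_CLASS)[AA_CLASS == class]
  sum(profile@probs[position, members]) > threshold
}

#' Conserved class of a profile position
#'
#' @inheritParams classConserved
#' @return the single class whose mass exceeds the threshold, or NA when
#'   none does (at most one class can exceed 0.5)
#' @export
conservedClass <- function(profile, position, threshold = 0.5) {
  for (cl in AA_CLASSES)
    if (classConserved(profile, position, cl, threshold)) return(cl)
  NA_character_
}

canonicalTriangle <- function(labels, edges) {
  # edges[i] is the edge opposite vertex i; minimize over vertex orders
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  keys <- vapply(perms, function(p)
    paste(c(labels[p], edges[p]), collapse = "|"), character(1))
  min(keys)
}

#' Extract labeled planar shapes from a residue neighborhood
#'
#' Enumerates segments (two vertices) and triangles (three vertices) among
#' residue representative points in the neighborhood sphere, labels
#' non-target vertices with their class (Ch/Hy/Po) and canonicalizes each
#' shape (sorted labels, edge lengths discretized into bins of
#' \code{binWidth} and sorted) so that congruent shapes share one key.
#' In the default (best-performing) configuration every shape is anchored
#' at the target residue, which carries a distinguished label, and the
#' remaining vertices are residues whose class is evolutionarily conserved
#' at their profile position; when \code{connectedOnly}, every vertex pair
#' of a shape must be closer than \code{connectDist} (default 5 Angstrom).
#'
#' @param nbh a \code{\linkS4class{StructuralNeighborhood}}
#' @param profile a \code{\linkS4class{ConservationProfile}} whose rows
#'   align with the residues of the neighborhood's structure
#' @param requireTargetVertex anchor every shape at the target (default)
#' @param connectedOnly require all pairwise vertex distances below
#'   \code{connectDist} (default)
#' @param conservedOnly use only class-conserved residues as non-target
#'   vertices, labeled by their conserved class (default); otherwise every
#'   member residue is eligible, labeled by its own amino-acid class
#' @param binWidth edge-length bin width, Angstrom
#' @param connectDist connectivity threshold, Angstrom
#' @param conservedThreshold class-mass threshold for conservation
#' @return a \code{\linkS4class{ShapeSet}}
#' @export
extractShapes <- function(nbh, profile, requireTargetVertex = TRUE,
                          connectedOnly = TRUE, conservedOnly = TRUE,
                          binWidth = 1, connectDist = 5,
                          conservedThreshold = 0.5) {
  stopifnot(is(nbh, "StructuralNeighborhood"),
            is(profile, "ConservationProfile"))
  opts <- list(requireTargetVertex = requireTargetVertex,
               connectedOnly = connectedOnly,
               conservedOnly = conservedOnly, binWidth = binWidth,
               connectDist = connectDist,
               conservedThreshold = conservedThreshold)
  st <- nbh@structure
  others <- setdiff(nbh@memberIndex, nbh@targetIndex)

  labs <- character(0)
  keep <- integer(0)
  for (i in others) {
    cl <- if (conservedOnly)
      conservedClass(profile, i, conservedThreshold)
    else aaClass(st@residues$aa[i])
    if (!is.na(cl)) {
      keep <- c(keep, i)
      labs <- c(labs, SHAPE_CLASS_ABBR[[cl]])
    }
  }

  counts <- integer(0)
  addShape <- function(key) {
    if (key %in% names(counts)) counts[key] <<- counts[key] + 1L
    else counts[key] <<- 1L
  }

  if (length(keep)) {
    pts <- matrix(NA_real_, length(keep), 3)
    for (k in seq_along(keep))
      pts[k, ] <- representativePoint(st, keep[k])
    tp <- representativePoint(st, nbh@targetIndex)
    dT <- sqrt(colSums((t(pts) - tp)^2))
    bin <- function(d) floor(d / binWidth)

    if (requireTargetVertex) {
      for (k in seq_along(keep)) {
        if (connectedOnly && dT[k] >= connectDist) next
        addShape(paste("S", labs[k], bin(dT[k]), sep = "|"))
      }
      if (length(keep) >= 2L) {
        for (k1 in seq_len(length(keep) - 1L)) {
          for (k2 in seq(k1 + 1L, length(keep))) {
            d12 <- sqrt(sum((pts[k1, ] - pts[k2, ])^2))
            if (connectedOnly &&
                (dT[k1] >= connectDist || dT[k2] >= connectDist ||
                 d12 >= connectDist)) next
            v <- order(paste(labs[c(k1, k2)],
                             bin(dT[c(k1, k2)]), sep = ":"))
            pair <- c(k1, k2)[v]
            addShape(paste("T",
                           paste(labs[pair[1]], bin(dT[pair[1]]), sep = ":"),
                           paste(labs[pair[2]], bin(dT[pair[2]]), sep = ":"),
                           bin(d12), sep = "|"))
          }
        }
      }
    } else {
      # unanchored variant: shapes among eligible residues themselves
      for (k1 in seq_len(length(keep))) {
        for (k2 in seq_len(length(keep))) {
          if (k2 <= k1) next
          d12 <- sqrt(sum((pts[k1, ] - pts[k2, ])^2))
          if (connectedOnly && d12 >= connectDist) next
          ll <- sort(labs[c(k1, k2)])
          addShape(paste("S", ll[1], ll[2], bin(d12), sep = "|"))
        }
      }
      if (length(keep) >= 3L) {
        combs <- utils::combn(length(keep), 3)
        for (ci in seq_len(ncol(combs))) {
          tri <- combs[, ci]
          e <- c(sqrt(sum((pts[tri[2], ] - pts[tri[3], ])^2)),
                 sqrt(sum((pts[tri[1], ] - pts[tri[3], ])^2)),
                 sqrt(sum((pts[tri[1], ] - pts[tri[2], ])^2)))
          if (connectedOnly && any(e >= connectDist)) next
          addShape(paste("T", canonicalTriangle(labs[tri], bin(e)),
                         sep = "|"))
        }
      }
    }
  }
  new("ShapeSet", counts = counts, options = opts)
}

#' Decomposition kernel between two shape sets
#'
#' Similarity of two residues measured as the number of shapes shared
#' between their neighborhoods: the dot product of the canonical-shape
#' count vectors, \eqn{K(a, b) = \sum_s c_a(s) c_b(s)}. Positive
#' semidefinite by construction. Both sets must have been extracted with
#' identical options.
#'
#' @param a,b \code{\linkS4class{ShapeSet}} objects
#' @return non-negative scalar
#' @export
shapeKernel <- function(a, b) {
  stopifnot(is(a, "ShapeSet"), is(b, "ShapeSet"))
  if (!identical(a@options, b@options))
    stop("shape sets were extracted with different options")
  common <- intersect(names(a@counts), names(b@counts))
  if (!length(common)) return(0)
  sum(as.numeric(a@counts[common]) * as.numeric(b@counts[common]))
}

#' Gram matrix of the shape kernel
#'
#' Pairwise decomposition-kernel matrix over a list of shape sets,
#' optionally combined with a base kernel matrix as
#' \eqn{K = K_{base} + \lambda K_{shape}} (\eqn{\lambda \ge 0}).
#'
#' @param shapeSets list of \code{\linkS4class{ShapeSet}}
#' @param base optional square base kernel matrix of matching dimension
#' @param lambda non-negative weight of the shape kernel in the combination
#' @return symmetric positive semidefinite matrix
#' @export
gramMatrix <- function(shapeSets, base = NULL, lambda = 1) {
  if (lambda < 0) stop("lambda must be non-negative")
  n <- length(shapeSets)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      K[i, j] <- K[j, i] <- shapeKernel(shapeSets[[i]], shapeSets[[j]])
    }
  }
  if (!is.null(base)) {
    stopifnot(all(dim(base) == c(n, n)))
    K <- base + lambda * K
  } else if (lambda != 1) {
    K <- lambda * K
  }
  K
}

#' Serialize a shape set to a text file
#'
#' One line per canonical shape: key and count, tab separated. The options
#' are stored in header comments so deserialized sets remain comparable.
#'
#' @param x a \code{\linkS4class{ShapeSet}}
#' @param file output path
#' @return invisibly, the path
#' @export
writeShapeSet <- function(x, file) {
  stopifnot(is(x, "ShapeSet"))
  hdr <- vapply(names(x@options), function(k)
    sprintf("#opt %s=%s", k, format(x@options[[k]])), character(1))
  body <- if (length(x@counts))
    paste(names(x@counts), x@counts, sep = "\t") else character(0)
  writeLines(c("#catres-shapeset v1", hdr, body), file)
  invisible(file)
}

#' Read a serialized shape set
#'
#' @param file path written by \code{\link{writeShapeSet}}
#' @return a \code{\linkS4class{ShapeSet}}
#' @export
readShapeSet <- function(file) {
  lines <- readLines(file, warn = FALSE)
  if (!length(lines) || lines[1L] != "#catres-shapeset v1")
    stop("not a catres shape-set file")
  optLines <- grep("^#opt ", lines, value = TRUE)
  opts <- list()
  for (l in optLines) {
    kv <- strsplit(sub("^#opt ", "", l), "=", fixed = TRUE)[[1L]]
    v <- kv[2L]
    opts[[kv[1L]]] <- if (v %in% c("TRUE", "FALSE")) as.logical(v)
                      else as.numeric(v)
  }
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  counts <- integer(0)
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    counts <- setNames(as.integer(vapply(parts, `[`, character(1), 2L)),
                       vapply(parts, `[`, character(1), 1L))
  }
  new("ShapeSet", counts = counts, options = opts)
}
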