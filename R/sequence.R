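#' One-hot encoding of the amino-acid identity
#'
#' 20-bit one-hot vector in alphabetical one-letter order (A..Y). The
#' unknown code 'X' maps to the all-zero vector.
#'
#' @param aa one-letter amino-acid code (standard 20 or 'X')
#' @return named numeric vector of 20 bits
#' @export
encodeAaName <- function(aa) {
  if (!(aa %in% c(AA_ALPHABET, "X")))
    stop(sprintf("'%s' is not a standard one-letter amino-acid code", aa))
  out <- setNames(numeric(20), paste0("aa.", AA_ALPHABET))
  if (aa != "X") out[paste0("aa.", aa)] <- 1
  out
}

#' One-hot encoding of the amino-acid class
#'
#' Three-bit one-hot over the physico-chemical partition: H, R, K, E, D
#' charged; Q, T, S, N, C, Y, W polar; G, F, L, M, A, I, P, V hydrophobic.
#' 'X' maps to the all-zero vector.
#'
#' @param aa one-letter amino-acid code (standard 20 or 'X')
#' @return named numeric vector of 3 bits (charged, polar, hydrophobic)
#' @export
encodeAaClass <- function(aa) {
  if (!(aa %in% c(AA_ALPHABET, "X")))
    stop(sprintf("'%s' is not a standard one-letter amino-acid code", aa))
  out <- setNames(numeric(3), paste0("class.", AA_CLASSES))
  if (aa != "X") out[paste0("class.", AA_CLASS[[aa]])] <- 1
  out
}

#' Class of an amino acid
#' @param aa one-letter code
#' @return "charged", "polar" or "hydrophobic" (NA for 'X')
#' @export
aaClass <- function(aa) {
  if (aa == "X") return(NA_character_)
  unname(AA_CLASS[aa])
}

#' Construct a conservation profile from a probability matrix
#'
#' @param probs L x 20 matrix of per-position amino-acid probabilities;
#'   columns either named with one-letter codes or assumed to be in
#'   alphabetical order. Rows are renormalized to sum to 1.
#' @param nObs effective number of observed sequences per position
#'   (recycled; NA when unknown)
#' @return a \code{\linkS4class{ConservationProfile}}
#' @export
newProfile <- function(probs, nObs = NA_real_) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 20L) stop("profile matrix must have 20 columns")
  if (!is.null(colnames(probs)) && all(AA_ALPHABET %in% colnames(probs)))
    probs <- probs[, AA_ALPHABET, drop = FALSE]
  colnames(probs) <- AA_ALPHABET
  s <- rowSums(probs)
  if (any(s <= 0)) stop("profile rows must have positive mass")
  probs <- probs / s
  new("ConservationProfile", probs = probs,
      nObs = rep_len(as.numeric(nObs), nrow(probs)))
}

# PSI-Blast ASCII PSSM column order (codes as printed by blastpgp/psiblast)
PSSM_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "V", "Y")

#' Read a conservation profile
#'
#' Supports two dialects:
#' \itemize{
#'   \item the package TSV dialect: first line \code{#catres-profile v1},
#'     then one row per residue with 20 probability columns (alphabetical
#'     order) and an optional 21st \code{n_obs} column;
#'   \item PSI-Blast ASCII PSSM output: the 20 percentage columns
#'     (weighted observed frequencies) are converted to probabilities and
#'     renormalized. Rows whose percentages do not sum to 100 +- 1 are
#'     renormalized with a warning. The effective observation count is not
#'     part of this format, so \code{nObs} is NA and the reliability
#'     weight of those positions is 0.
#' }
#'
#' @param file path to a profile file
#' @return a \code{\linkS4class{ConservationProfile}}
#' @export
readProfile <- function(file) {
  lines <- readLines(file, warn = FALSE)
  if (length(lines) && startsWith(lines[1L], "#catres-profile")) {
    body <- lines[-1L]
    body <- body[nzchar(trimws(body))]
    fields <- strsplit(trimws(body), "[\t ]+")
    nf <- lengths(fields)
    if (!all(nf %in% c(20L, 21L)))
      stop("profile TSV rows must have 20 probability columns (+ optional n_obs)")
    vals <- suppressWarnings(lapply(fields, as.numeric))
    if (anyNA(unlist(vals))) stop("non-numeric value in profile TSV")
    probs <- t(vapply(vals, function(v) v[1:20], numeric(20)))
    nObs <- vapply(vals, function(v)
      if (length(v) == 21L) v[21L] else NA_real_, numeric(1))
    return(newProfile(probs, nObs))
  }
  readPSSM(lines)
}

readPSSM <- function(lines) {
  # data rows: position index, residue letter, 20 log-odds, 20 percentages
  dat <- grepl("^\\s*\\d+\\s+[A-Z]\\s", lines)
  if (!any(dat)) stop("unrecognized profile format")
  fields <- strsplit(trimws(lines[dat]), "\\s+")
  nf <- lengths(fields)
  if (!all(nf >= 42L))
    stop("PSSM rows must carry 20 log-odds and 20 percentage columns")
  pct <- t(vapply(fields, function(v) {
    x <- suppressWarnings(as.numeric(v[23:42]))
    if (anyNA(x)) stop("non-numeric value in PSSM percentages")
    x
  }, numeric(20)))
  bad <- abs(rowSums(pct) - 100) > 1
  if (any(bad))
    warning(sprintf("%d PSSM row(s) do not sum to 100; renormalized",
                    sum(bad)))
  zero <- rowSums(pct) <= 0
  if (any(zero)) pct[zero, ] <- 1  # uniform fallback for all-zero rows
  colnames(pct) <- PSSM_ORDER
  pct <- pct[, AA_ALPHABET, drop = FALSE]
  newProfile(pct / rowSums(pct))
}

#' Per-position profile entropy
#'
#' Shannon entropy of the 20-way distribution in bits,
#' \eqn{-\sum_a p_a \log_2 p_a} with \eqn{0 \log 0 := 0}. Ranges from 0
#' (one-hot, fully conserved) to \eqn{\log_2 20 \approx 4.32} (uniform).
#'
#' @param profile a \code{\linkS4class{ConservationProfile}}
#' @param position optional position index; default all positions
#' @return numeric vector of entropies (bits)
#' @export
profileEntropy <- function(profile, position = NULL) {
  stopifnot(is(profile, "ConservationProfile"))
  p <- profile@probs
  if (!is.null(position)) p <- p[position, , drop = FALSE]
  plogp <- ifelse(p > 0, p * log2(p), 0)
  as.numeric(-rowSums(plogp))
}

#' Per-position profile reliability weight
#'
#' Pseudocount-based reliability of the profile,
#' \eqn{w = n / (n + \beta)} where \eqn{n} is the effective number of
#' observed sequences at the position. 0 when nothing was observed (or the
#' source format does not report observation counts), approaching 1 for
#' deep alignments; \eqn{w = 0.5} exactly when \eqn{n = \beta}.
#'
#' @param profile a \code{\linkS4class{ConservationProfile}}
#' @param position optional position index; default all positions
#' @param beta pseudocount mass (> 0, default 10)
#' @return numeric vector of weights in [0, 1]
#' @export
profileWeight <- function(profile, position = NULL, beta = 10) {
  stopifnot(is(profile, "ConservationProfile"), beta > 0)
  n <- profile@nObs
  if (!is.null(position)) n <- n[position]
  w <- n / (n + beta)
  w[is.na(w)] <- 0
  as.numeric(w)
}

#' Windowed profile encoding
#'
#' Concatenates the per-position encoding (20 probabilities, entropy,
#' reliability weight: 22 values) of positions \code{i - w .. i + w} along
#' the primary sequence. Positions falling outside the sequence are padded
#' with zeros, so the output length is always \code{(2w + 1) * 22}.
#'
#' @param profile a \code{\linkS4class{ConservationProfile}}
#' @param position center position index (1-based)
#' @param w residues per side (w = 0 gives the unwindowed 22 values)
#' @param beta pseudocount mass for the reliability weight
#' @return named numeric vector of length \code{(2w + 1) * 22}
#' @export
windowProfile <- function(profile, position, w = 0, beta = 10) {
  stopifnot(is(profile, "ConservationProfile"), w >= 0)
  L <- nrow(profile@probs)
  ent <- profileEntropy(profile)
  wt <- profileWeight(profile, beta = beta)
  out <- numeric(0)
  for (off in seq(-w, w)) {
    j <- position + off
    block <- if (j >= 1 && j <= L)
      c(profile@probs[j, ], entropy = ent[j], weight = wt[j])
    else setNames(numeric(22), c(AA_ALPHABET, "entropy", "weight"))
    names(block) <- paste0("prof", off, ".", c(AA_ALPHABET, "entropy", "weight"))
    out <- c(out, block)
  }
  out
}

#' Write a profile in the package TSV dialect
#'
#' @param profile a \code{\linkS4class{ConservationProfile}}
#' @param file output path
#' @return invisibly, the path
#' @export
writeProfile <- function(profile, file) {
  stopifnot(is(profile, "ConservationProfile"))
  rows <- apply(cbind(profile@probs,
                      ifelse(is.na(profile@nObs), NA, profile@nObs)),
                1, function(v) {
    v <- v[!is.na(v)]
    paste(formatC(v, format = "g", digits = 10), collapse = "\t")
  })
  writeLines(c("#catres-profile v1", rows), file)
  invisible(file)
}
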