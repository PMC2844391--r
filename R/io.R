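#' Read a per-residue catalytic-label file
#'
#' CSV with columns \code{id, label, protein_PDB_Id, residue, chain,
#' number}: \code{label} is +1 for residues annotated as catalytic and -1
#' otherwise, \code{residue} the one-letter code, \code{chain} the chain
#' identifier ('A' when the PDB file reports none) and \code{number} the
#' author residue number.
#'
#' @param file path to a labels CSV
#' @return data.frame with the six columns, label coerced to integer
#' @export
readLabels <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("id", "label", "protein_PDB_Id", "residue", "chain", "number")
  if (!all(need %in% names(df)))
    stop(sprintf("labels file must have columns: %s",
                 paste(need, collapse = ", ")))
  df$label <- as.integer(df$label)
  if (!all(df$label %in% c(1L, -1L)))
    stop("labels must be +1 or -1")
  df$chain <- as.character(df$chain)
  df
}

#' Write a labels data.frame
#' @param labels data.frame as returned by \code{\link{readLabels}}
#' @param file output path
#' @return invisibly, the path
#' @export
writeLabels <- function(labels, file) {
  utils::write.csv(labels, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Audit a labels file
#'
#' Summary counts of a per-residue label set: total rows, number of
#' positive (catalytic) residues, number of distinct proteins, and the
#' negative-to-positive ratio.
#'
#' @param labels a labels data.frame or a file path
#' @return named list \code{nResidues}, \code{nPositive}, \code{nProteins},
#'   \code{negPosRatio}
#' @export
auditLabels <- function(labels) {
  if (is.character(labels)) labels <- readLabels(labels)
  list(nResidues = nrow(labels),
       nPositive = sum(labels$label == 1L),
       nProteins = length(unique(labels$protein_PDB_Id)),
       negPosRatio = classImbalanceRatio(labels))
}

#' Read an external per-residue attribute table
#'
#' Tab-separated table of precomputed third-party attributes keyed by
#' residue: columns \code{protein_PDB_Id}, \code{chain}, \code{number},
#' then one numeric column per attribute. Used to plug external feature
#' sets into \code{\link{assembleFeatures}} via an
#' \code{external:<name>} block.
#'
#' @param file path to a TSV file
#' @return data.frame with the key columns and numeric attribute columns
#' @export
readAttributeTable <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("protein_PDB_Id", "chain", "number")
  if (!all(need %in% names(df)))
    stop("attribute table must carry protein_PDB_Id, chain, number keys")
  df$chain <- as.character(df$chain)
  df
}

#' Write a feature table in SVMlight sparse format
#'
#' One line per residue: \code{label index:value ...} with 1-based feature
#' indices and zero-valued features omitted.
#'
#' @param features feature table from \code{\link{assembleFeatures}}
#' @param file output path
#' @return invisibly, the path
#' @export
writeSVMlight <- function(features, file) {
  X <- featureMatrix(features)
  y <- features$label
  lines <- vapply(seq_len(nrow(X)), function(i) {
    nz <- which(X[i, ] != 0 & !is.na(X[i, ]))
    paste(c(sprintf("%+d", y[i]),
            sprintf("%d:%.10g", nz, X[i, nz])), collapse = " ")
  }, character(1))
  writeLines(lines, file)
  invisible(file)
}

#' Write per-residue predictions as TSV
#'
#' @param predictions data.frame with columns \code{protein}, \code{chain},
#'   \code{number}, \code{residue}, \code{score}, \code{predicted}
#' @param file output path
#' @return invisibly, the path
#' @export
writePredictions <- function(predictions, file) {
  utils::write.table(predictions, file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}

#' Write an averaged curve as TSV
#'
#' @param curve result of \code{\link{averagedROC}} / \code{\link{averagedRP}}
#' @param file output path
#' @return invisibly, the path
#' @export
writeCurveTSV <- function(curve, file) {
  df <- curve$curve
  df$n <- curve$nProteins
  utils::write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write a Gram matrix as dense TSV
#'
#' @param K square matrix from \code{\link{gramMatrix}}
#' @param file output path
#' @return invisibly, the path
#' @export
writeGramTSV <- function(K, file) {
  utils::write.table(K, file, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a key-value configuration file
#'
#' Plain-text configuration: one \code{key = value} pair per line, comments
#' starting with \code{#}. Values are parsed as numeric vectors when
#' possible (comma separated), otherwise kept as strings. Documented keys:
#' \code{radius}, \code{w}, \code{beta}, \code{k}, \code{innerK},
#' \code{cost}, \code{jGrid}, \code{seed}, \code{binWidth},
#' \code{connectDist}.
#'
#' @param file path to a config file
#' @return named list of values
#' @export
readConfig <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  out <- list()
  for (l in lines) {
    kv <- strsplit(l, "=", fixed = TRUE)[[1L]]
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else val
  }
  out
}
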