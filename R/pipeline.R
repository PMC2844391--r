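FEATURE_BLOCKS <- c("1D1", "1D2", "1D3", "3D1", "3D2", "3D3", "3D4",
                    "3D5", "3D6", "3D7", "3D8", "3D9")

# run code under a fixed seed without disturbing the caller's RNG stream
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

metaColumns <- c("protein", "chain", "number", "insert", "residue", "label")

#' Assemble per-residue feature vectors
#'
#' Builds the named, ordered feature table for every residue of the given
#' structures from the registered feature blocks:
#' \tabular{lll}{
#'   1D1 \tab 20 \tab amino-acid identity one-hot \cr
#'   1D2 \tab 3 \tab amino-acid class one-hot \cr
#'   1D3 \tab (2w+1)*22 \tab conservation profile + entropy + weight \cr
#'   3D1 \tab 12 \tab physico-chemical three-bin distributions \cr
#'   3D2 \tab 20 \tab neighborhood amino-acid composition \cr
#'   3D3 \tab 3 \tab charge counts (positive, negative, sum) \cr
#'   3D4 \tab 1 \tab water count \cr
#'   3D5 \tab 1 \tab atomic density \cr
#'   3D6 \tab 1 \tab normalized B-factor \cr
#'   3D7 \tab 1 \tab disulphide-bonded cysteine flag \cr
#'   3D8 \tab 3 \tab heterogen-class counts \cr
#'   3D9 \tab 1 \tab cofactor bond flag \cr
#'   external:<name> \tab any \tab columns of a registered attribute table
#' }
#' Blocks appear in the order given; the within-block order is fixed as
#' documented in each block's function. Residues missing from an external
#' table get NA values (imputed later by the normalizer) with a warning.
#'
#' @param structures list of \code{\linkS4class{ProteinStructure}}
#' @param profiles named list of \code{\linkS4class{ConservationProfile}},
#'   one per structure (names = pdbId), rows aligned with residues;
#'   required when a 1D3 block (or shape conservation) is requested
#' @param labels optional labels data.frame (see \code{\link{readLabels}});
#'   unmatched residues get label NA (unknown)
#' @param blocks character vector of block names
#' @param radius neighborhood sphere radius, Angstrom
#' @param w profile window half-width (residues per side; 0 = no window)
#' @param beta pseudocount mass for the profile reliability weight
#' @param includeTarget include the target residue in neighborhood
#'   statistics (default TRUE)
#' @param externalTables named list of attribute tables
#'   (\code{\link{readAttributeTable}}) for \code{external:} blocks
#' @return data.frame: key columns \code{protein, chain, number, insert,
#'   residue, label} followed by the feature columns
#' @export
assembleFeatures <- function(structures, profiles = NULL, labels = NULL,
                             blocks = FEATURE_BLOCKS, radius = 8, w = 0,
                             beta = 10, includeTarget = TRUE,
                             externalTables = list()) {
  stopifnot(length(blocks) >= 1)
  known <- blocks %in% FEATURE_BLOCKS | startsWith(blocks, "external:")
  if (!all(known))
    stop(sprintf("unknown feature block(s): %s",
                 paste(blocks[!known], collapse = ", ")))
  rows <- list()
  for (ps in structures) {
    pid <- ps@pdbId
    prof <- if (!is.null(profiles)) profiles[[pid]] else NULL
    if (any(blocks == "1D3") && is.null(prof))
      stop(sprintf("block 1D3 requested but no profile for %s", pid))
    n <- nResidues(ps)
    rp <- representativePoints(ps)
    bz <- normalizedBfactor(ps)
    needNbh <- any(blocks %in% c("3D1", "3D2", "3D3", "3D4", "3D5", "3D8"))
    for (i in seq_len(n)) {
      nbh <- if (needNbh)
        buildNeighborhood(ps, i, radius, repPoints = rp) else NULL
      feat <- numeric(0)
      for (b in blocks) {
        feat <- c(feat, switch(b,
          "1D1" = encodeAaName(ps@residues$aa[i]),
          "1D2" = encodeAaClass(ps@residues$aa[i]),
          "1D3" = windowProfile(prof, i, w = w, beta = beta),
          "3D1" = physchemDistribution(nbh, includeTarget),
          "3D2" = setNames(aaComposition(nbh, includeTarget),
                           paste0("aafreq.", AA_ALPHABET)),
          "3D3" = chargeFeatures(nbh, includeTarget),
          "3D4" = c(waterCount = as.numeric(waterCount(nbh))),
          "3D5" = c(atomicDensity = as.numeric(atomicDensity(nbh))),
          "3D6" = c(bfactorZ = bz[i]),
          "3D7" = c(ssFlag = disulphideFlag(ps, i)),
          "3D8" = heterogenCounts(nbh),
          "3D9" = c(cofactorBond = cofactorBondFlag(ps, i)),
          externalBlockValues(b, externalTables, ps, i)))
      }
      rows[[length(rows) + 1L]] <- c(
        list(protein = pid, chain = ps@residues$chain[i],
             number = ps@residues$resno[i],
             insert = ps@residues$insert[i],
             residue = ps@residues$aa[i], label = NA_integer_),
        as.list(feat))
    }
  }
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)))
  rownames(out) <- NULL
  if (!is.null(labels)) {
    key <- paste(out$protein, out$chain, out$number)
    lkey <- paste(labels$protein_PDB_Id, labels$chain, labels$number)
    out$label <- labels$label[match(key, lkey)]
  }
  out
}

externalBlockValues <- function(block, externalTables, ps, i) {
  name <- sub("^external:", "", block)
  tab <- externalTables[[name]]
  if (is.null(tab))
    stop(sprintf("external table '%s' not registered", name))
  cols <- setdiff(names(tab), c("protein_PDB_Id", "chain", "number"))
  hit <- which(tab$protein_PDB_Id == ps@pdbId &
                 tab$chain == ps@residues$chain[i] &
                 tab$number == ps@residues$resno[i])
  if (!length(hit)) {
    warning(sprintf("residue %s %s%d absent from external table '%s'",
                    ps@pdbId, ps@residues$chain[i], ps@residues$resno[i],
                    name))
    return(setNames(rep(NA_real_, length(cols)),
                    paste0(name, ".", cols)))
  }
  setNames(as.numeric(tab[hit[1L], cols]), paste0(name, ".", cols))
}

#' Numeric feature matrix of an assembled table
#'
#' @param features table from \code{\link{assembleFeatures}}
#' @return numeric matrix of the feature columns (key columns dropped)
#' @export
featureMatrix <- function(features) {
  cols <- setdiff(names(features), metaColumns)
  as.matrix(features[, cols, drop = FALSE])
}

#' Fit normalization and imputation statistics
#'
#' Per numeric feature: training minimum, maximum and mean (the mean is
#' the imputation value, applied before scaling); per feature flagged
#' categorical: the mode. Statistics must be fitted on the training split
#' of the current fold only, never on its test residues. Features that are
#' entirely missing in training are dropped with a warning.
#'
#' @param X numeric training matrix (NAs = missing)
#' @param categorical names of columns to impute by mode instead of mean
#' @return a \code{catresNormalizer} list
#' @export
fitNormalizer <- function(X, categorical = character(0)) {
  X <- as.matrix(X)
  allMissing <- colSums(!is.na(X)) == 0
  if (any(allMissing)) {
    warning(sprintf("dropping all-missing feature(s): %s",
                    paste(colnames(X)[allMissing], collapse = ", ")))
    X <- X[, !allMissing, drop = FALSE]
  }
  stats <- lapply(seq_len(ncol(X)), function(jc) {
    v <- X[, jc]
    obs <- v[!is.na(v)]
    fill <- if (colnames(X)[jc] %in% categorical) {
      tab <- table(obs)
      as.numeric(names(tab)[which.max(tab)])  # mode; ties -> smallest
    } else mean(obs)
    list(min = min(obs), max = max(obs), fill = fill)
  })
  names(stats) <- colnames(X)
  structure(list(stats = stats, features = colnames(X)),
            class = "catresNormalizer")
}

#' Apply normalization and imputation
#'
#' Missing values are imputed with the training fill value (mean or mode),
#' then each feature is linearly mapped so that the training range becomes
#' [-1, +1]: \eqn{v' = 2 (v - min) / (max - min) - 1}. Values outside the
#' training range are clipped to [-1, 1]; features constant in training
#' map to 0.
#'
#' @param normalizer from \code{\link{fitNormalizer}}
#' @param X numeric matrix with the same feature columns
#' @return normalized matrix restricted to the normalizer's features
#' @export
applyNormalizer <- function(normalizer, X) {
  stopifnot(inherits(normalizer, "catresNormalizer"))
  X <- as.matrix(X)[, normalizer$features, drop = FALSE]
  for (jc in seq_len(ncol(X))) {
    s <- normalizer$stats[[jc]]
    v <- X[, jc]
    v[is.na(v)] <- s$fill
    if (s$max > s$min) {
      v <- 2 * (v - s$min) / (s$max - s$min) - 1
      v <- pmin(1, pmax(-1, v))
    } else {
      v <- rep(0, length(v))
    }
    X[, jc] <- v
  }
  X
}

#' Protein-stratified fold assignment
#'
#' Shuffles the proteins with the given seed and deals them round-robin
#' over k folds, so that all residues of a protein share a fold and fold
#' sizes differ by at most one protein.
#'
#' @param proteins character vector of protein identifiers (de-duplicated)
#' @param k number of folds (default 10)
#' @param seed RNG seed for the shuffle
#' @return data.frame \code{protein}, \code{fold}
#' @export
makeFolds <- function(proteins, k = 10, seed = 1) {
  proteins <- unique(as.character(proteins))
  if (k < 2) stop("k must be at least 2")
  if (length(proteins) < k)
    stop("need at least k proteins for k folds")
  shuffled <- withSeed(seed, sample(proteins))
  data.frame(protein = shuffled,
             fold = rep_len(seq_len(k), length(shuffled)),
             stringsAsFactors = FALSE)
}

#' Train a class-weighted linear SVM
#'
#' Soft-margin linear SVM (libsvm via \pkg{e1071}) in which training
#' errors on positive examples are weighted \code{j} times those on
#' negatives (the cost factor), compensating the strong class imbalance of
#' the catalytic-residue task. The model exposes an explicit weight vector
#' and bias: the decision score of a residue x is \eqn{w \cdot x + b}, and
#' the hard label is its sign (threshold 0).
#'
#' @param X normalized numeric feature matrix
#' @param y vector of +1/-1 labels (both classes required)
#' @param cost regularization parameter C (default 1)
#' @param j cost factor multiplying the error weight of positives
#' @return a \code{catresSVM} object with elements \code{w} (named weight
#'   vector), \code{b}, \code{cost}, \code{j}
#' @export
trainLinearSVM <- function(X, y, cost = 1, j = 1) {
  X <- as.matrix(X)
  if (length(unique(y)) < 2L)
    stop("training data must contain both classes")
  stopifnot(all(y %in% c(-1, 1)), cost > 0, j > 0)
  yf <- factor(y, levels = c(-1, 1))
  fit <- e1071::svm(x = X, y = yf, type = "C-classification",
                    kernel = "linear", cost = cost, scale = FALSE,
                    class.weights = c("-1" = 1, "1" = j))
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # libsvm orients the decision value toward the first internal label;
  # flip so that positive score always means the +1 class
  firstLevel <- levels(yf)[fit$labels[1L]]
  if (firstLevel == "-1") {
    w <- -w
    b <- -b
  }
  names(w) <- colnames(X)
  structure(list(w = w, b = b, cost = cost, j = j),
            class = "catresSVM")
}

#' Predict with a linear SVM
#'
#' @param object a \code{catresSVM} model
#' @param X normalized feature matrix (columns matching the model weights)
#' @param ... unused
#' @return data.frame \code{score} (\eqn{w \cdot x + b}) and
#'   \code{predicted} (+1 when score > 0, else -1)
#' @export
predict.catresSVM <- function(object, X, ...) {
  X <- as.matrix(X)[, names(object$w), drop = FALSE]
  score <- drop(X %*% object$w) + object$b
  data.frame(score = score,
             predicted = ifelse(score > 0, 1L, -1L))
}

#' Ranked feature-weight report
#'
#' Features of a trained linear model sorted by decreasing absolute
#' weight; components with the largest magnitude are the most discriminant
#' directions of the separating hyperplane (sign tells whether the feature
#' pushes toward or away from the catalytic class).
#'
#' @param model a \code{catresSVM}
#' @return data.frame \code{feature}, \code{weight}, ordered by |weight|
#' @export
weightReport <- function(model) {
  stopifnot(inherits(model, "catresSVM"))
  ord <- order(abs(model$w), decreasing = TRUE)
  data.frame(feature = names(model$w)[ord], weight = unname(model$w[ord]),
             stringsAsFactors = FALSE)
}

fitPredictSplit <- function(train, test, cost, j) {
  Xtr <- featureMatrix(train)
  norm <- fitNormalizer(Xtr)
  model <- trainLinearSVM(applyNormalizer(norm, Xtr), train$label,
                          cost = cost, j = j)
  pred <- predict(model, applyNormalizer(norm, featureMatrix(test)))
  list(model = model, normalizer = norm, pred = pred)
}

#' Tune the SVM cost factor by inner cross-validation
#'
#' Evaluates each candidate cost factor j by protein-stratified inner
#' cross-validation inside the training set and returns the value
#' maximizing the mean inner-fold F1 (the model-selection criterion); ties
#' are broken toward the smallest j. Grid values that never produce a
#' positive prediction score F1 = 0.
#'
#' @param train assembled (un-normalized) feature table of the training
#'   fold; normalization is re-fitted inside every inner split
#' @param jGrid candidate cost factors (all > 0)
#' @param innerK number of inner folds (default 5)
#' @param seed seed for the inner fold assignment
#' @param cost SVM regularization parameter (default 1)
#' @return list \code{j} (selected value) and \code{meanF1} (named vector
#'   of mean inner-CV F1 per grid value)
#' @export
tuneCostFactor <- function(train, jGrid = c(1, 2, 5, 10, 20, 50, 100, 200),
                           innerK = 5, seed = 1, cost = 1) {
  stopifnot(length(jGrid) >= 1, all(jGrid > 0))
  jGrid <- sort(unique(jGrid))
  if (length(jGrid) == 1L)
    return(list(j = jGrid, meanF1 = setNames(NA_real_, jGrid)))
  if (!all(c(1, -1) %in% train$label))
    stop("training fold must contain both classes")
  prots <- unique(train$protein)
  innerK <- min(innerK, length(prots))
  folds <- makeFolds(prots, k = innerK, seed = seed)
  f1 <- matrix(NA_real_, nrow = innerK, ncol = length(jGrid),
               dimnames = list(NULL, jGrid))
  for (f in seq_len(innerK)) {
    testProts <- folds$protein[folds$fold == f]
    tr <- train[!(train$protein %in% testProts), , drop = FALSE]
    te <- train[train$protein %in% testProts, , drop = FALSE]
    if (!all(c(1, -1) %in% tr$label) || nrow(te) == 0) next
    for (ji in seq_along(jGrid)) {
      res <- fitPredictSplit(tr, te, cost, jGrid[ji])
      f1[f, ji] <- labelMetrics(res$pred$predicted, te$label)[["f1"]]
    }
  }
  meanF1 <- colMeans(f1, na.rm = TRUE)
  meanF1[is.nan(meanF1)] <- 0
  list(j = jGrid[which.max(meanF1)], meanF1 = meanF1)
}

#' Protein-stratified cross-validation of the catalytic-residue SVM
#'
#' Full evaluation protocol: residues are split into k folds at the
#' protein level (all residues of a protein share a fold); inside every
#' training split the cost factor j is tuned by inner cross-validation,
#' normalization/imputation statistics are fitted on the training split
#' only, a class-weighted linear SVM is trained and the held-out residues
#' are scored.
#'
#' @param features assembled feature table with labels (+1/-1)
#' @param k number of outer folds (default 10)
#' @param seed seed controlling fold assignment (outer and inner)
#' @param jGrid candidate cost factors; a single value disables tuning
#' @param innerK inner folds for the cost-factor search
#' @param cost SVM regularization parameter (default 1)
#' @return list with:
#'   \itemize{
#'     \item \code{predictions}: per-residue data.frame (protein, chain,
#'       number, residue, fold, score, predicted, label);
#'     \item \code{perFold}: per-fold data.frame (fold, j, precision,
#'       recall, fpr, f1, mcc);
#'     \item \code{summary}: mean and s.d. of the per-fold metrics;
#'     \item \code{folds}: the protein-to-fold assignment;
#'     \item \code{models}, \code{normalizers}: per-fold fitted objects
#'       (for weight inspection and leakage audits).
#'   }
#' @examples
#' \donttest{
#' ens <- generateEnsemble(nProteins = 10, nResidues = 60, seed = 1)
#' feats <- assembleFeatures(ens$structures, ens$profiles, ens$labels)
#' cv <- crossValidate(feats, k = 5, seed = 1, jGrid = c(1, 10))
#' cv$summary
#' }
#' @export
crossValidate <- function(features, k = 10, seed = 1,
                          jGrid = c(1, 2, 5, 10, 20, 50, 100, 200),
                          innerK = 5, cost = 1) {
  stopifnot(all(features$label %in% c(-1L, 1L)))
  folds <- makeFolds(unique(features$protein), k = k, seed = seed)
  preds <- list()
  perFold <- list()
  models <- list()
  normalizers <- list()
  for (f in seq_len(k)) {
    testProts <- folds$protein[folds$fold == f]
    train <- features[!(features$protein %in% testProts), , drop = FALSE]
    test <- features[features$protein %in% testProts, , drop = FALSE]
    jStar <- if (length(jGrid) > 1L)
      tuneCostFactor(train, jGrid = jGrid, innerK = innerK,
                     seed = seed + f, cost = cost)$j
    else jGrid
    res <- fitPredictSplit(train, test, cost, jStar)
    m <- labelMetrics(res$pred$predicted, test$label)
    perFold[[f]] <- data.frame(fold = f, j = jStar, t(m))
    preds[[f]] <- data.frame(
      protein = test$protein, chain = test$chain, number = test$number,
      residue = test$residue, fold = f, score = res$pred$score,
      predicted = res$pred$predicted, label = test$label,
      stringsAsFactors = FALSE)
    models[[f]] <- res$model
    normalizers[[f]] <- res$normalizer
  }
  perFold <- do.call(rbind, perFold)
  metricCols <- c("precision", "recall", "fpr", "f1", "mcc")
  summary <- data.frame(
    metric = metricCols,
    mean = vapply(metricCols, function(mc) mean(perFold[[mc]]), numeric(1)),
    sd = vapply(metricCols, function(mc) stats::sd(perFold[[mc]]),
                numeric(1)),
    row.names = NULL)
  list(predictions = do.call(rbind, preds), perFold = perFold,
       summary = summary, folds = folds, models = models,
       normalizers = normalizers)
}
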