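# Cross-validated performance estimation, the exact McNemar test on
# discordant classifications, and the first (dimension) regularization.

#' Cross-validate CPPLS + LDA over a range of dimensions
#'
#' For each fold, fits CPPLS with up to `maxComponents` components on the
#' training part and classifies the held-out samples with the a-component
#' model for every a = 1..A, recording per-sample correctness. The per-fold
#' coefficient vectors are retained for the jackknife q-value criterion.
#' k-fold folds are stratified by class; leave-one-out holds out single
#' samples.
#'
#' If a fold's fit stops early (degenerate component), dimensions beyond
#' the available count reuse the largest fitted model.
#'
#' @param data a [LabeledDataset-class].
#' @param maxComponents largest dimension A to try
#'   (A <= min(n_train - 1, p)).
#' @param scheme `"loo"` or `"kfold"`.
#' @param folds number of folds for `"kfold"`.
#' @param seed optional seed for the fold shuffle (k-fold only).
#' @param gammaRegions,gridSize passed to [fitCppls()].
#' @return a [CorrectnessRecord-class].
#' @examples
#' sim <- syntheticClassification(nPerClass = 12, p = 10, nInformative = 3,
#'                                delta = 3, seed = 7)
#' crossValidate(sim$data, maxComponents = 2)
#' @export
crossValidate <- function(data, maxComponents, scheme = c("loo", "kfold"),
                          folds = 10L, seed = NULL,
                          gammaRegions = .defaultGammaRegions(),
                          gridSize = 5L) {
  stopifnot(is(data, "LabeledDataset"))
  scheme <- match.arg(scheme)
  n <- nrow(data@X); p <- ncol(data@X)
  assign <- if (scheme == "loo") seq_len(n)
            else .stratifiedFolds(data@classes, folds, seed)
  m <- max(assign)
  A <- as.integer(maxComponents)
  ntrainMin <- n - max(tabulate(assign, m))
  if (A < 1L || A > min(ntrainMin - 1L, p))
    stop("maxComponents must be in 1..min(n_train - 1, p)")
  correct <- matrix(0L, n, A,
                    dimnames = list(rownames(data@X), paste0("a", 1:A)))
  foldBetas <- vector("list", m)
  labels <- as.character(data@classes)
  for (fold in seq_len(m)) {
    test <- which(assign == fold)
    train <- which(assign != fold)
    if (nlevels(droplevels(data@classes[train])) < 2L)
      stop("a fold's training part lost a class; cannot cross-validate")
    dtr <- data[train, ]
    kf <- min(A, length(train) - 1L, p)
    fit <- fitCppls(dtr, kf, gammaRegions, gridSize)
    kAvail <- fit@nComponents
    B <- matrix(0, p, A, dimnames = list(colnames(data@X), paste0("a", 1:A)))
    for (a in seq_len(A)) {
      aUse <- min(a, kAvail)
      B[, a] <- .cpplsBeta(fit@W, fit@P1, fit@p2, aUse)
      str <- predictScores(fit, dtr@X, aUse)
      ste <- predictScores(fit, data@X[test, , drop = FALSE], aUse)
      pred <- ldaClassify(str, dtr@classes, ste)
      correct[test, a] <- as.integer(pred == labels[test])
    }
    foldBetas[[fold]] <- B
  }
  new("CorrectnessRecord", correct = correct, P = colMeans(correct),
      scheme = scheme, foldAssignment = as.integer(assign),
      foldBetas = foldBetas)
}

# Class-stratified fold assignment; shuffles within class, then deals
# samples round-robin so every fold keeps both classes (as far as counts
# allow).
.stratifiedFolds <- function(classes, folds, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(classes)
  folds <- as.integer(folds)
  if (folds < 2L || folds > n) stop("folds must be in 2..n")
  assign <- integer(n)
  offset <- 0L
  for (lev in levels(classes)) {
    idx <- sample(which(classes == lev))
    assign[idx] <- ((seq_along(idx) + offset - 1L) %% folds) + 1L
    offset <- offset + length(idx)
  }
  assign
}

#' Exact one-sided McNemar test on paired correctness vectors
#'
#' Tests whether a candidate classifier is worse than a reference using
#' only the discordant samples: with b = #\{candidate correct, reference
#' wrong\} and c = #\{candidate wrong, reference correct\}, the p-value is
#' the exact binomial tail P(Bin(b + c, 1/2) <= b) for the alternative
#' that the candidate's correct-classification probability is smaller.
#' Samples where both classifiers agree are ignored; with no discordant
#' pairs the p-value is 1.
#'
#' @param correctCand,correctRef 0/1 vectors of equal length.
#' @return p-value in (0, 1].
#' @examples
#' mcnemarPvalue(c(0, 0, 1, 1), c(1, 1, 1, 1))  # b = 0, c = 2
#' @export
mcnemarPvalue <- function(correctCand, correctRef) {
  if (length(correctCand) != length(correctRef))
    stop("correctness vectors must have equal length")
  if (!all(correctCand %in% c(0, 1)) || !all(correctRef %in% c(0, 1)))
    stop("correctness vectors must be 0/1")
  b <- sum(correctCand == 1 & correctRef == 0)
  cc <- sum(correctCand == 0 & correctRef == 1)
  if (b + cc == 0L) return(1)
  stats::pbinom(b, b + cc, 0.5)
}

#' First regularization: estimate the model dimension
#'
#' Finds a* as the dimension with maximal cross-validated performance
#' (smallest a on ties) and returns the smallest a <= a* whose held-out
#' correctness is not significantly worse than a*'s by the one-sided
#' McNemar test at rejection level `cLevel`. Large `cLevel` (near 1)
#' rejects easily and keeps the estimate near a*; small `cLevel`
#' regularizes harder toward few components.
#'
#' @param record a [CorrectnessRecord-class].
#' @param cLevel rejection level c in (0, 1].
#' @return list with `aHat`, `aStar` and the vector of per-dimension
#'   `pValues` against a*.
#' @export
estimateDimension <- function(record, cLevel) {
  stopifnot(is(record, "CorrectnessRecord"))
  if (cLevel <= 0 || cLevel > 1) stop("cLevel must be in (0, 1]")
  P <- record@P
  aStar <- which.max(P)                       # smallest a on ties
  pv <- vapply(seq_len(aStar), function(a)
    mcnemarPvalue(record@correct[, a], record@correct[, aStar]), 1.0)
  aHat <- aStar
  for (a in seq_len(aStar)) {
    if (pv[a] >= cLevel) { aHat <- a; break }
  }
  list(aHat = as.integer(aHat), aStar = as.integer(aStar), pValues = pv)
}

# Pick the rejection level c from a grid by maximizing the cross-validated
# performance attained at the regularized dimension; smallest c on ties.
.chooseC <- function(record, cGrid) {
  cGrid <- sort(cGrid)
  best <- NULL
  for (cl in cGrid) {
    est <- estimateDimension(record, cl)
    perf <- record@P[est$aHat]
    if (is.null(best) || perf > best$perf + 1e-15) {
      best <- list(cLevel = cl, aHat = est$aHat, aStar = est$aStar,
                   perf = perf)
    }
  }
  best
}
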