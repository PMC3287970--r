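# Outer evaluation protocol: repeated stratified 75/25 splits, the
# selectivity-score stability measure, and its permutation null.

# One stratified split into test (testFraction) and training rows.
.stratifiedSplit <- function(classes, testFraction) {
  test <- integer(0)
  for (lev in levels(classes)) {
    idx <- which(classes == lev)
    nTest <- max(1L, round(length(idx) * testFraction))
    test <- c(test, sample(idx, nTest))
  }
  sort(test)
}

#' Repeated split evaluation of the selection pipeline
#'
#' Draws `nReps` independent stratified test/training partitions (default
#' 25%/75%; test and training never overlap within a repetition), runs
#' [tuneAndSelect()] on each training part, and evaluates the refitted
#' classifier on the held-out test part. For each repetition the full
#' model's and the optimum iteration's test performances are recorded too,
#' so selected-versus-optimum comparisons need no extra runs.
#'
#' @param data a [LabeledDataset-class].
#' @param nReps number of repetitions.
#' @param testFraction fraction of samples held out per repetition.
#' @param criterion,u,fGrid,dGrid,cGrid,maxComponents,folds,gammaRegions,gridSize
#'   passed to [tuneAndSelect()].
#' @param seed seed governing all splits and fold shuffles.
#' @return list with `summary` (data.frame: selected size, train/test
#'   performance of the selected, optimum and full models per repetition)
#'   and `selections` (list of selected-id character vectors).
#' @export
repeatedSplitEvaluation <- function(data, nReps = 100L, testFraction = 0.25,
                                    criterion = c("vip", "loading", "qvalue"),
                                    u = defaultCutoff(criterion),
                                    fGrid = 0.5, dGrid = 0.01, cGrid = 0.5,
                                    maxComponents = 3L, folds = 10L,
                                    seed = NULL,
                                    gammaRegions = .defaultGammaRegions(),
                                    gridSize = 5L) {
  stopifnot(is(data, "LabeledDataset"))
  criterion <- match.arg(criterion)
  if (!is.null(seed)) set.seed(seed)
  labels <- as.character(data@classes)
  selections <- vector("list", nReps)
  rows <- vector("list", nReps)
  for (rep in seq_len(nReps)) {
    test <- .stratifiedSplit(data@classes, testFraction)
    train <- setdiff(seq_len(nrow(data@X)), test)
    dtr <- data[train, ]
    res <- tuneAndSelect(dtr, criterion, u, fGrid, dGrid, cGrid,
                         maxComponents, folds, seed = NULL,
                         gammaRegions = gammaRegions, gridSize = gridSize)
    Xte <- data@X[test, , drop = FALSE]
    predSel <- predict(res, Xte)
    # optimum-iteration model (g*) refit
    selStar <- res@trace@iterations[[res@gStar]]$retained
    refitStar <- .refitSelected(dtr, selStar, cGrid, maxComponents,
                                gammaRegions, gridSize)
    predStar <- .classifyNew(refitStar, Xte)
    # full model (no elimination)
    refitFull <- .refitSelected(dtr, colnames(data@X), cGrid, maxComponents,
                                gammaRegions, gridSize)
    predFull <- .classifyNew(refitFull, Xte)
    trainScores <- predictScores(res@fit, dtr@X[, res@selected, drop = FALSE],
                                 min(res@aHat, res@fit@nComponents))
    trainPred <- .ldaPredict(res@ldaModel, trainScores)
    selections[[rep]] <- res@selected
    rows[[rep]] <- data.frame(
      rep = rep,
      nSelected = length(res@selected),
      trainPerf = mean(trainPred == labels[train]),
      testPerf = mean(predSel == labels[test]),
      testPerfOptimum = mean(predStar == labels[test]),
      testPerfFull = mean(predFull == labels[test]),
      f = res@f, d = res@d, aHat = res@aHat)
  }
  list(summary = do.call(rbind, rows), selections = selections)
}

#' Selectivity score of repeated selections
#'
#' A variable selected as one of m variables in a repetition earns 1/m;
#' scores are summed per variable and divided by the number of
#' repetitions. A method that homes in on the same few variables yields a
#' few large scores; a diffuse method spreads many small ones. The profile
#' sums to 1 over variables.
#'
#' @param selections list of character vectors of selected variable ids,
#'   one per repetition; all nonempty.
#' @param variableIds the full variable-id universe (length p).
#' @return a [SelectivityProfile-class].
#' @examples
#' selectivityScore(list(c("V1", "V2"), "V1"), paste0("V", 1:4))
#' @export
selectivityScore <- function(selections, variableIds) {
  if (!length(selections)) stop("no selections given")
  sizes <- lengths(selections)
  if (any(sizes == 0L)) stop("empty selection in a repetition")
  scores <- stats::setNames(numeric(length(variableIds)), variableIds)
  for (sel in selections) {
    idx <- match(sel, variableIds)
    if (anyNA(idx)) stop("selection contains unknown variable ids")
    scores[idx] <- scores[idx] + 1 / length(sel)
  }
  new("SelectivityProfile", scores = scores / length(selections),
      nReps = length(selections), perRepSizes = as.integer(sizes))
}

#' Permutation null distribution of the selectivity score
#'
#' Repeats the whole selection-stability computation on data whose class
#' labels have been randomly permuted, pooling the per-variable
#' selectivity scores across permutations, and returns the empirical upper
#' percentile of the pooled null scores (default the upper 0.1%). Real
#' variables whose selectivity exceeds this threshold are selected more
#' stably than chance.
#'
#' @param data a [LabeledDataset-class].
#' @param nPerm number of label permutations.
#' @param nReps repetitions of the split evaluation per permutation.
#' @param level upper-tail probability of the reported threshold.
#' @param seed seed governing permutations and splits.
#' @inheritParams repeatedSplitEvaluation
#' @return list with `nullScores` (pooled per-variable scores over all
#'   permutations), `threshold` and `level`.
#' @export
permutationNull <- function(data, nPerm = 10L, nReps = 10L, level = 0.001,
                            criterion = c("vip", "loading", "qvalue"),
                            u = defaultCutoff(criterion),
                            fGrid = 0.5, dGrid = 0.01, cGrid = 0.5,
                            maxComponents = 3L, folds = 10L, seed = NULL,
                            gammaRegions = .defaultGammaRegions(),
                            gridSize = 5L) {
  stopifnot(is(data, "LabeledDataset"))
  criterion <- match.arg(criterion)
  if (nPerm < 1L) stop("nPerm must be >= 1")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  pooled <- NULL
  for (b in seq_len(nPerm)) {
    perm <- sample(seq_len(nrow(data@X)))
    dperm <- LabeledDataset(data@X, data@classes[perm],
                            positiveClass = data@positiveClass)
    ev <- repeatedSplitEvaluation(dperm, nReps, 0.25, criterion, u,
                                  fGrid, dGrid, cGrid, maxComponents,
                                  folds, seed = NULL,
                                  gammaRegions = gammaRegions,
                                  gridSize = gridSize)
    prof <- selectivityScore(ev$selections, colnames(data@X))
    pooled <- c(pooled, prof@scores)
  }
  list(nullScores = pooled,
       threshold = as.numeric(stats::quantile(pooled, 1 - level)),
       level = level)
}
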