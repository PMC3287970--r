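# The regularized greedy backward-elimination loop, the second (final
# iteration) regularization, and 10-fold tuning of the fraction f and
# rejection level d.

#' Default extreme cutoff u for each criterion
#'
#' The elimination loop is run with u at an extreme value so that flagging
#' is permissive and the McNemar regularizations, not the cutoff, decide
#' where to stop: 0.99 for loading weights, 0.01 for q-values, 10 for VIP.
#'
#' @param criterion `"loading"`, `"qvalue"` or `"vip"`.
#' @return numeric cutoff.
#' @export
defaultCutoff <- function(criterion = c("vip", "loading", "qvalue")) {
  switch(match.arg(criterion), loading = 0.99, qvalue = 0.01, vip = 10)
}

# One elimination iteration's worth of model fitting: LOO cross-validation
# on the current columns, dimension estimate (choosing c from a grid if one
# is given), full-data refit at the estimated dimension, criterion values.
.iterationModel <- function(data, criterion, cLevels, maxComponents,
                            gammaRegions, gridSize) {
  n <- nrow(data@X); p <- ncol(data@X)
  A <- max(1L, min(maxComponents, n - 2L, p))
  rec <- crossValidate(data, A, scheme = "loo",
                       gammaRegions = gammaRegions, gridSize = gridSize)
  est <- if (length(cLevels) > 1L) .chooseC(rec, cLevels)
         else c(estimateDimension(rec, cLevels), list(cLevel = cLevels))
  if (is.null(est$cLevel)) est$cLevel <- cLevels
  aHat <- est$aHat
  fit <- fitCppls(data, aHat, gammaRegions, gridSize)
  aUse <- min(aHat, fit@nComponents)
  crit <- switch(criterion,
    loading = criterionLoadingWeights(fit, aUse),
    vip = criterionVip(fit, aUse),
    qvalue = {
      fb <- lapply(rec@foldBetas, function(B) B[, aHat])
      criterionCoefficientQvalues(fb, coefficients(fit, aUse))
    })
  list(rec = rec, aHat = aHat, cLevel = est$cLevel, fit = fit, crit = crit)
}

#' Regularized backward elimination
#'
#' Greedy loop over variable subsets Z_g. Each iteration runs leave-one-out
#' cross-validated CPPLS + LDA on the current columns, estimates the
#' dimension with the first McNemar regularization at level `cLevel`
#' (a grid is resolved per iteration by maximizing cross-validated
#' performance, smallest c on ties), computes the chosen importance
#' criterion on a full-data fit at that dimension (q-values use the
#' leave-one-out fold coefficients), flags the M variables beyond the
#' cutoff `u`, and eliminates the `N = ceiling(f * M)` most extreme ones
#' (ties broken by ascending variable index). The loop stops when M = 0 or
#' a single variable remains; the last variable is never eliminated.
#'
#' @param data a [LabeledDataset-class].
#' @param criterion `"vip"`, `"loading"` or `"qvalue"`.
#' @param u flagging cutoff; defaults to [defaultCutoff()] of the criterion.
#' @param f elimination fraction in (0, 1]; small f takes small steps.
#' @param cLevel rejection level c of the dimension regularization, or a
#'   grid of candidate levels resolved per iteration.
#' @param maxComponents largest dimension tried per iteration.
#' @param gammaRegions,gridSize passed to [fitCppls()].
#' @return an [EliminationTrace-class]; iteration g records the columns of
#'   Z_g and the performance of the regularized model on them.
#' @examples
#' sim <- syntheticClassification(nPerClass = 10, p = 15, nInformative = 3,
#'                                delta = 3, seed = 2)
#' tr <- eliminate(sim$data, "vip", f = 0.5, maxComponents = 2)
#' as.data.frame(tr)
#' @export
eliminate <- function(data, criterion = c("vip", "loading", "qvalue"),
                      u = defaultCutoff(criterion), f = 0.5,
                      cLevel = 0.5, maxComponents = 3L,
                      gammaRegions = .defaultGammaRegions(),
                      gridSize = 5L) {
  stopifnot(is(data, "LabeledDataset"))
  criterion <- match.arg(criterion)
  if (f <= 0 || f > 1) stop("f must lie in (0, 1]")
  p <- ncol(data@X)
  ids <- colnames(data@X)
  retained <- seq_len(p)
  iterations <- list()
  repeat {
    Zg <- data[, retained]
    mod <- .iterationModel(Zg, criterion, cLevel, maxComponents,
                           gammaRegions, gridSize)
    flagged <- flagForElimination(mod$crit, u)
    M <- length(flagged)
    N <- if (M > 0L) as.integer(ceiling(f * M)) else 0L
    pg <- length(retained)
    # never empty the model: keep at least the single best variable
    if (N >= pg) N <- pg - 1L
    iterations[[length(iterations) + 1L]] <- list(
      retained = ids[retained],
      P = mod$rec@P[mod$aHat],
      correct = as.integer(mod$rec@correct[, mod$aHat]),
      aHat = mod$aHat, cLevel = mod$cLevel,
      M = M, N = N)
    if (M == 0L || N == 0L) break
    drop <- .extremeOrder(mod$crit, flagged)[seq_len(N)]
    retained <- retained[-drop]
    if (length(retained) <= 1L) break
  }
  new("EliminationTrace", iterations = iterations, variableIds = ids,
      criterion = criterion)
}

#' Second regularization: choose the final elimination iteration
#'
#' Finds the optimum iteration g* with maximal performance P_g (largest g
#' on ties, favouring the smaller model) and returns the largest g >= g*
#' whose held-out correctness is not significantly worse than g*'s by the
#' one-sided McNemar test at level `d`. Small `d` sacrifices performance
#' for simplicity; the per-iteration p-values beyond g* are returned to
#' expose the trade-off.
#'
#' @param trace an [EliminationTrace-class].
#' @param d rejection level in (0, 1].
#' @return list with `gFinal`, `gStar` (1-based iteration indices into the
#'   trace), `selected` (variable ids of iteration gFinal) and `pValues`
#'   (named, iterations g* and beyond against g*).
#' @export
chooseFinalIteration <- function(trace, d) {
  stopifnot(is(trace, "EliminationTrace"))
  if (d <= 0 || d > 1) stop("d must be in (0, 1]")
  its <- trace@iterations
  P <- vapply(its, function(it) it$P, 1.0)
  gStar <- max(which(P == max(P)))            # largest g on ties
  gs <- seq.int(gStar, length(its))
  pv <- vapply(gs, function(g)
    mcnemarPvalue(its[[g]]$correct, its[[gStar]]$correct), 1.0)
  names(pv) <- paste0("g", gs - 1L)
  ok <- gs[pv >= d]
  gFinal <- if (length(ok)) max(ok) else gStar
  list(gFinal = as.integer(gFinal), gStar = as.integer(gStar),
       selected = its[[gFinal]]$retained, pValues = pv)
}

# Refit the classifier on a chosen variable subset: re-estimate the
# dimension on the reduced columns, fit CPPLS and the LDA rule on all rows.
.refitSelected <- function(data, selected, cLevels, maxComponents,
                           gammaRegions = .defaultGammaRegions(),
                           gridSize = 5L) {
  sub <- data[, selected]
  mod <- .iterationModel(sub, "loading", cLevels, maxComponents,
                         gammaRegions, gridSize)
  fit <- mod$fit
  scores <- predictScores(fit, sub@X, min(mod$aHat, fit@nComponents))
  lda <- .ldaTrain(scores, sub@classes)
  list(fit = fit, ldaModel = lda, aHat = mod$aHat, cLevel = mod$cLevel,
       selected = selected)
}

# Classify new rows with a refitted (fit, ldaModel) pair on the selected
# columns of Xnew (matched by name).
.classifyNew <- function(refit, Xnew) {
  Xs <- Xnew[, refit$selected, drop = FALSE]
  sc <- predictScores(refit$fit, Xs,
                      min(refit$aHat, refit$fit@nComponents))
  .ldaPredict(refit$ldaModel, sc)
}

#' Tune f and d by 10-fold cross-validation and select variables
#'
#' For every pair (f, d) on the grids, runs the elimination and the second
#' regularization on each fold's training part, refits the CPPLS + LDA
#' classifier on the selected variables and scores the held-out fold. The
#' pair with the highest mean held-out performance wins (ties prefer the
#' larger f, then the smaller d, i.e. fewer variables); the winning pair
#' is then rerun on the full training data to produce the final selection.
#' With singleton grids the tuning loop is skipped. The rejection level c
#' of the inner (dimension) regularization is resolved per iteration from
#' `cGrid` by the leave-one-out performance rule.
#'
#' @param train a [LabeledDataset-class].
#' @param criterion,u,maxComponents,gammaRegions,gridSize see [eliminate()].
#' @param fGrid,dGrid,cGrid candidate grids for f, d and c.
#' @param folds fold count of the tuning cross-validation.
#' @param seed seed for the fold shuffle.
#' @return a [SelectionResult-class].
#' @export
tuneAndSelect <- function(train, criterion = c("vip", "loading", "qvalue"),
                          u = defaultCutoff(criterion),
                          fGrid = c(0.1, 0.5, 1), dGrid = c(0.01, 0.99),
                          cGrid = c(0.1, 0.5, 1), maxComponents = 3L,
                          folds = 10L, seed = NULL,
                          gammaRegions = .defaultGammaRegions(),
                          gridSize = 5L) {
  stopifnot(is(train, "LabeledDataset"))
  criterion <- match.arg(criterion)
  fGrid <- sort(unique(fGrid)); dGrid <- sort(unique(dGrid))
  best <- list(f = fGrid[length(fGrid)], d = dGrid[1L])
  if (length(fGrid) > 1L || length(dGrid) > 1L) {
    assign <- .stratifiedFolds(train@classes, min(folds, nrow(train@X) %/% 2L),
                               seed)
    labels <- as.character(train@classes)
    perf <- matrix(0, length(fGrid), length(dGrid),
                   dimnames = list(paste0("f", fGrid), paste0("d", dGrid)))
    for (fold in seq_len(max(assign))) {
      tr <- which(assign != fold); te <- which(assign == fold)
      dtr <- train[tr, ]
      for (i in seq_along(fGrid)) {
        trace <- eliminate(dtr, criterion, u, fGrid[i], cGrid,
                           maxComponents, gammaRegions, gridSize)
        for (j in seq_along(dGrid)) {
          sel <- chooseFinalIteration(trace, dGrid[j])$selected
          refit <- .refitSelected(dtr, sel, cGrid, maxComponents,
                                  gammaRegions, gridSize)
          pred <- .classifyNew(refit, train@X[te, , drop = FALSE])
          perf[i, j] <- perf[i, j] + sum(pred == labels[te])
        }
      }
    }
    # ties: larger f, then smaller d
    bestVal <- max(perf)
    cand <- which(perf >= bestVal - 1e-12, arr.ind = TRUE)
    cand <- cand[order(-cand[, 1L], cand[, 2L]), , drop = FALSE]
    best <- list(f = fGrid[cand[1L, 1L]], d = dGrid[cand[1L, 2L]])
  }
  trace <- eliminate(train, criterion, u, best$f, cGrid, maxComponents,
                     gammaRegions, gridSize)
  fin <- chooseFinalIteration(trace, best$d)
  refit <- .refitSelected(train, fin$selected, cGrid, maxComponents,
                          gammaRegions, gridSize)
  new("SelectionResult",
      selected = fin$selected, fit = refit$fit, ldaModel = refit$ldaModel,
      f = best$f, d = best$d, cLevel = refit$cLevel,
      aHat = as.integer(refit$aHat),
      gStar = fin$gStar, gFinal = fin$gFinal, pValues = fin$pValues,
      trace = trace)
}

#' Classify new samples with a selection result
#'
#' @param object a [SelectionResult-class].
#' @param newdata numeric matrix containing (at least) the selected
#'   columns, matched by name.
#' @param ... ignored.
#' @return character vector of predicted class labels.
#' @export
setMethod("predict", "SelectionResult", function(object, newdata, ...) {
  .classifyNew(list(fit = object@fit, ldaModel = object@ldaModel,
                    aHat = object@aHat, selected = object@selected),
               as.matrix(newdata))
})
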