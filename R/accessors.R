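# Constructors, accessors and show methods for the core classes.

#' Construct a two-class labeled dataset
#'
#' @param X numeric matrix, samples in rows, variables in columns. Row and
#'   column names are used as sample and variable ids (generated if absent).
#' @param classes vector (factor, character or otherwise coercible) of
#'   class labels, one per row of `X`; exactly two distinct values.
#' @param positiveClass the label to dummy-code as 1. Defaults to the
#'   second factor level.
#'
#' @return A [LabeledDataset-class] object.
#' @examples
#' X <- matrix(rnorm(40), 10, 4)
#' ld <- LabeledDataset(X, rep(c("ctrl", "case"), 5), positiveClass = "case")
#' dummyResponse(ld)
#' @export
LabeledDataset <- function(X, classes, positiveClass = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(rownames(X))) rownames(X) <- paste0("S", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  classes <- as.factor(as.character(classes))
  if (is.null(positiveClass)) positiveClass <- levels(classes)[2L]
  y <- dummyEncode(classes, positiveClass)
  new("LabeledDataset", X = X, classes = classes, y = as.numeric(y),
      positiveClass = as.character(positiveClass))
}

#' @describeIn LabeledDataset predictor matrix
#' @param object,x a `LabeledDataset`
#' @export
predictorMatrix <- function(object) object@X

#' @describeIn LabeledDataset class label factor
#' @export
classLabels <- function(object) object@classes

#' @describeIn LabeledDataset 0/1 dummy response
#' @export
dummyResponse <- function(object) object@y

#' @describeIn LabeledDataset the class label coded as 1
#' @export
positiveClass <- function(object) object@positiveClass

#' @describeIn LabeledDataset variable ids
#' @export
variableIds <- function(object) {
  if (is(object, "LabeledDataset")) colnames(object@X) else object@variableIds
}

#' Subset the variables of a labeled dataset
#'
#' @param x a [LabeledDataset-class]
#' @param i sample index (rows); missing keeps all
#' @param j variable index (columns); missing keeps all
#' @param ... ignored
#' @param drop ignored; dimensions are always kept
#' @return a `LabeledDataset` on the chosen samples/variables
#' @export
setMethod("[", "LabeledDataset", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@X))
  if (missing(j)) j <- seq_len(ncol(x@X))
  LabeledDataset(x@X[i, j, drop = FALSE], droplevels(x@classes[i]),
                 positiveClass = x@positiveClass)
})

setMethod("dim", "LabeledDataset", function(x) dim(x@X))

setMethod("show", "LabeledDataset", function(object) {
  tab <- table(object@classes)
  cat("LabeledDataset:", nrow(object@X), "samples x", ncol(object@X),
      "variables\n")
  cat("  classes:", paste(sprintf("%s (%d)", names(tab), tab),
                          collapse = ", "),
      "| positive:", object@positiveClass, "\n")
})

#' @describeIn CpplsFit loading-weight matrix W
#' @param object a `CpplsFit`
#' @export
loadingWeights <- function(object) object@W

#' @describeIn CpplsFit X-loading matrix P1
#' @export
xLoadings <- function(object) object@P1

#' @describeIn CpplsFit y-loading vector p2
#' @export
yLoadings <- function(object) object@p2

#' @describeIn CpplsFit component score matrix T
#' @export
componentScores <- function(object) object@scores

#' @describeIn CpplsFit selected power parameters, one per component
#' @export
selectedGammas <- function(object) object@gammas

#' Regression coefficients of a CPPLS fit
#'
#' Coefficient vector of the model truncated to the first `a` components,
#' computed as W_a (P1_a' W_a)^{-1} p2_a.
#'
#' @param object a [CpplsFit-class]
#' @param a number of components to use (default: all)
#' @return named numeric p-vector
#' @export
setMethod("coefficients", "CpplsFit", function(object,
                                               a = object@nComponents) {
  .cpplsBeta(object@W, object@P1, object@p2, a, object@variableIds)
})

setMethod("show", "CpplsFit", function(object) {
  cat("CpplsFit:", length(object@beta), "variables,",
      object@nComponents, "component(s)\n")
  cat("  gammas:", paste(signif(object@gammas, 3), collapse = ", "), "\n")
  if (object@degenerate)
    cat("  note: component extraction stopped early (degenerate score)\n")
})

setMethod("show", "CorrectnessRecord", function(object) {
  cat("CorrectnessRecord (", object@scheme, "): ",
      nrow(object@correct), " samples x ", ncol(object@correct),
      " dimension(s)\n", sep = "")
  cat("  P_a:", paste(sprintf("%.3f", object@P), collapse = " "), "\n")
})

setMethod("show", "CriterionVector", function(object) {
  cat("CriterionVector '", object@kind, "' (", object@direction, "), ",
      length(object@values), " variables\n", sep = "")
})

#' @describeIn CriterionVector numeric criterion values
#' @param object a `CriterionVector`
#' @export
criterionValues <- function(object) object@values

#' Tabular view of an elimination trace
#'
#' @param x an [EliminationTrace-class]
#' @param ... ignored
#' @return data.frame with one row per iteration: retained-variable count
#'   p_g, performance P_g, estimated dimension, rejection level c used,
#'   flagged count M and eliminated count N.
#' @export
setMethod("as.data.frame", "EliminationTrace", function(x, ...) {
  its <- x@iterations
  data.frame(
    iteration = seq_along(its) - 1L,
    nVariables = vapply(its, function(it) length(it$retained), 1L),
    P = vapply(its, function(it) it$P, 1.0),
    aHat = vapply(its, function(it) it$aHat, 1L),
    cLevel = vapply(its, function(it) it$cLevel, 1.0),
    M = vapply(its, function(it) it$M, 1L),
    N = vapply(its, function(it) it$N, 1L)
  )
})

setMethod("show", "EliminationTrace", function(object) {
  df <- as.data.frame(object)
  cat("EliminationTrace (criterion:", object@criterion, "),",
      nrow(df), "iterations\n")
  print(utils::head(df, 8))
  if (nrow(df) > 8) cat("  ...\n")
})

#' @describeIn EliminationTrace performance P_g per iteration
#' @param object an `EliminationTrace`
#' @export
tracePerformance <- function(object)
  vapply(object@iterations, function(it) it$P, 1.0)

#' @describeIn EliminationTrace retained variable ids of one iteration
#' @param g iteration index (0-based, as in `as.data.frame`)
#' @export
retainedVariables <- function(object, g)
  object@iterations[[g + 1L]]$retained

#' @describeIn SelectionResult selected variable ids
#' @param object a `SelectionResult`
#' @export
selectedVariables <- function(object) object@selected

setMethod("show", "SelectionResult", function(object) {
  cat("SelectionResult:", length(object@selected), "variables selected\n")
  cat(sprintf("  f = %g, d = %g, c = %g, dimension = %d\n",
              object@f, object@d, object@cLevel, object@aHat))
  cat(sprintf("  trace: optimum at iteration %d (P = %.3f), final %d (P = %.3f)\n",
              object@gStar - 1L, object@trace@iterations[[object@gStar]]$P,
              object@gFinal - 1L, object@trace@iterations[[object@gFinal]]$P))
})

#' @describeIn SelectivityProfile per-variable stability scores
#' @param object a `SelectivityProfile`
#' @export
selectivityScores <- function(object) object@scores

setMethod("show", "SelectivityProfile", function(object) {
  cat("SelectivityProfile over", object@nReps, "repetitions;",
      sum(object@scores > 0), "of", length(object@scores),
      "variables ever selected\n")
  top <- sort(object@scores, decreasing = TRUE)
  print(utils::head(round(top[top > 0], 4), 10))
})
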