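#' @import methods
NULL

#' Two-class labeled dataset
#'
#' Container for a numeric predictor matrix together with a two-class label
#' vector and its 0/1 dummy coding. All model-fitting functions in the
#' package operate on this class. The dummy response is 1 for the positive
#' class and 0 for the other class.
#'
#' @slot X numeric matrix, n samples by p variables; no missing values.
#' @slot classes factor of length n with exactly two levels, both present.
#' @slot y numeric 0/1 dummy response of length n.
#' @slot positiveClass the class label coded as 1.
#'
#' @seealso [LabeledDataset()] for the constructor, [dummyEncode()].
#' @exportClass LabeledDataset
setClass("LabeledDataset",
  slots = c(
    X = "matrix",
    classes = "factor",
    y = "numeric",
    positiveClass = "character"
  )
)

setValidity("LabeledDataset", function(object) {
  msg <- character()
  X <- object@X
  if (!is.numeric(X)) msg <- c(msg, "X must be a numeric matrix")
  if (anyNA(X)) msg <- c(msg, "X contains missing values")
  if (nrow(X) < 4L) msg <- c(msg, "need at least 4 samples")
  if (ncol(X) < 1L) msg <- c(msg, "need at least 1 variable")
  if (length(object@classes) != nrow(X))
    msg <- c(msg, "length of classes must equal nrow(X)")
  if (nlevels(object@classes) != 2L)
    msg <- c(msg, "classes must have exactly two levels")
  if (any(tabulate(object@classes, nbins = 2L) == 0L))
    msg <- c(msg, "degenerate response: both classes must be present")
  if (length(object@y) != nrow(X))
    msg <- c(msg, "length of y must equal nrow(X)")
  if (!all(object@y %in% c(0, 1)))
    msg <- c(msg, "y must contain only 0 and 1")
  if (length(msg)) msg else TRUE
})

#' Fitted CPPLS regression model
#'
#' Result of [fitCppls()]: a Canonical Powered PLS regression of the 0/1
#' dummy response on column-centered predictors. Components are extracted
#' sequentially; each loading-weight vector has unit Euclidean norm and the
#' power parameter gamma chosen for it is recorded.
#'
#' @slot nComponents number of extracted components k.
#' @slot W p x k loading-weight matrix, unit-norm columns.
#' @slot P1 p x k matrix of X-loadings.
#' @slot p2 length-k vector of y-loadings.
#' @slot scores n x k matrix of component scores.
#' @slot gammas length-k vector of selected power parameters.
#' @slot beta length-p regression coefficient vector using all k components.
#' @slot xCenter,yCenter centering values removed before fitting.
#' @slot variableIds column names of the training predictors.
#' @slot degenerate TRUE if extraction stopped early because a component
#'   score vector was numerically zero.
#'
#' @seealso [fitCppls()], [predictScores()], [coefficients()]
#' @exportClass CpplsFit
setClass("CpplsFit",
  slots = c(
    nComponents = "integer",
    W = "matrix",
    P1 = "matrix",
    p2 = "numeric",
    scores = "matrix",
    gammas = "numeric",
    beta = "numeric",
    xCenter = "numeric",
    yCenter = "numeric",
    variableIds = "character",
    degenerate = "logical"
  )
)

setValidity("CpplsFit", function(object) {
  k <- object@nComponents
  if (k < 1L) return("a fit must have at least one component")
  if (ncol(object@W) != k || ncol(object@P1) != k ||
      length(object@p2) != k || length(object@gammas) != k)
    return("component slots have inconsistent dimensions")
  norms <- sqrt(colSums(object@W^2))
  if (any(abs(norms - 1) > 1e-8))
    return("loading-weight columns must have unit norm")
  TRUE
})

#' Cross-validated correctness record
#'
#' Per-sample, per-dimension 0/1 correctness of held-out classification,
#' produced by [crossValidate()]. Column a records whether each sample was
#' correctly classified by the a-component CPPLS + LDA model when held out;
#' the column mean is the cross-validated performance P_a. Per-fold
#' coefficient vectors are retained for the jackknife q-value criterion.
#'
#' @slot correct n x A 0/1 matrix of held-out correctness.
#' @slot P length-A vector of performances (column means).
#' @slot scheme "loo" or "kfold".
#' @slot foldAssignment integer fold id per sample.
#' @slot foldBetas list (one entry per fold) of p x A matrices; column a is
#'   the coefficient vector of the a-component model fitted without that
#'   fold.
#'
#' @seealso [crossValidate()], [estimateDimension()]
#' @exportClass CorrectnessRecord
setClass("CorrectnessRecord",
  slots = c(
    correct = "matrix",
    P = "numeric",
    scheme = "character",
    foldAssignment = "integer",
    foldBetas = "list"
  )
)

setValidity("CorrectnessRecord", function(object) {
  if (!all(object@correct %in% c(0, 1)))
    return("correctness entries must be 0/1")
  if (length(object@P) != ncol(object@correct))
    return("P must have one entry per dimension column")
  if (max(abs(object@P - colMeans(object@correct))) > 1e-12)
    return("P must equal the column means of the correctness matrix")
  TRUE
})

#' Variable-importance criterion vector
#'
#' One value per variable for one of the three elimination criteria:
#' relative loading weights (`"loading"`), jackknife coefficient q-values
#' (`"qvalue"`) or variable importance on projections (`"vip"`). The
#' direction slot records whether small or large values mark a variable
#' for elimination.
#'
#' @slot kind "loading", "qvalue" or "vip".
#' @slot values numeric p-vector of criterion values.
#' @slot direction "small_is_bad" (loading, vip) or "large_is_bad" (qvalue).
#'
#' @seealso [criterionLoadingWeights()], [criterionCoefficientQvalues()],
#'   [criterionVip()], [flagForElimination()]
#' @exportClass CriterionVector
setClass("CriterionVector",
  slots = c(kind = "character", values = "numeric", direction = "character")
)

setValidity("CriterionVector", function(object) {
  if (!object@kind %in% c("loading", "qvalue", "vip"))
    return("kind must be one of 'loading', 'qvalue', 'vip'")
  ok <- if (object@kind == "vip") all(object@values >= 0)
        else all(object@values >= 0 & object@values <= 1)
  if (!ok) return("criterion values outside the valid range")
  expected <- if (object@kind == "qvalue") "large_is_bad" else "small_is_bad"
  if (object@direction != expected)
    return("direction inconsistent with criterion kind")
  TRUE
})

#' Backward-elimination trace
#'
#' Ordered record of the greedy elimination loop. Iteration g holds the
#' retained variable ids (the columns of Z_g), the cross-validated
#' performance P_g of the regularized CPPLS model on Z_g, its per-sample
#' correctness vector, the estimated dimension, and the flag/elimination
#' counts M and N for that iteration.
#'
#' @slot iterations list; each element has fields `retained`, `P`,
#'   `correct`, `aHat`, `cLevel`, `M`, `N`.
#' @slot variableIds the original variable ids (columns of Z_0).
#' @slot criterion criterion kind used ("loading", "qvalue" or "vip").
#'
#' @seealso [eliminate()], [chooseFinalIteration()]
#' @exportClass EliminationTrace
setClass("EliminationTrace",
  slots = c(iterations = "list", variableIds = "character",
            criterion = "character")
)

setValidity("EliminationTrace", function(object) {
  if (!length(object@iterations)) return("trace must hold >= 1 iteration")
  sizes <- vapply(object@iterations, function(it) length(it$retained), 1L)
  if (any(diff(sizes) >= 0))
    return("retained-variable counts must strictly decrease")
  TRUE
})

#' Final variable-selection result
#'
#' Output of [tuneAndSelect()]: the selected variable subset, the CPPLS +
#' LDA classifier refitted on it, the tuned control parameters, and the
#' full elimination trace.
#'
#' @slot selected character vector of selected variable ids.
#' @slot fit refitted [CpplsFit-class] on the selected columns.
#' @slot ldaModel list describing the 1-D LDA rule on predicted dummies
#'   (training scores and labels).
#' @slot f,d,cLevel tuned elimination fraction and rejection levels.
#' @slot aHat estimated dimension of the refitted model.
#' @slot gStar,gFinal optimum-performance and chosen trace iterations.
#' @slot pValues McNemar p-values of iterations at and beyond gStar
#'   against gStar.
#' @slot trace the [EliminationTrace-class] on the full training data.
#'
#' @seealso [tuneAndSelect()], [predict,SelectionResult-method]
#' @exportClass SelectionResult
setClass("SelectionResult",
  slots = c(
    selected = "character",
    fit = "CpplsFit",
    ldaModel = "list",
    f = "numeric",
    d = "numeric",
    cLevel = "numeric",
    aHat = "integer",
    gStar = "integer",
    gFinal = "integer",
    pValues = "numeric",
    trace = "EliminationTrace"
  )
)

setValidity("SelectionResult", function(object) {
  if (!length(object@selected)) return("selected set must be nonempty")
  if (object@gFinal < object@gStar) return("gFinal must be >= gStar")
  TRUE
})

#' Selectivity-score stability profile
#'
#' Per-variable stability of repeated selections: a variable selected as
#' one of m variables in a repetition earns 1/m, and scores are averaged
#' over repetitions, so the profile sums to 1 when every repetition selects
#' at least one variable.
#'
#' @slot scores named numeric p-vector of mean per-repetition scores.
#' @slot nReps number of repetitions.
#' @slot perRepSizes selected-model size in each repetition.
#'
#' @seealso [selectivityScore()], [permutationNull()]
#' @exportClass SelectivityProfile
setClass("SelectivityProfile",
  slots = c(scores = "numeric", nReps = "integer", perRepSizes = "integer")
)

setValidity("SelectivityProfile", function(object) {
  if (any(object@scores < 0)) return("scores must be nonnegative")
  if (length(object@perRepSizes) != object@nReps)
    return("perRepSizes must have one entry per repetition")
  TRUE
})
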