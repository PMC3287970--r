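# Canonical Powered PLS core: dummy coding, powered loading weights,
# gamma search, sequential component extraction, prediction, and the 1-D
# LDA classifier on predicted dummy values.

#' Dummy-code a two-class label vector
#'
#' @param labels vector with exactly two distinct values.
#' @param positiveClass the label coded as 1.
#' @return numeric 0/1 vector of the same length.
#' @examples
#' dummyEncode(c("A", "B", "A"), "A")
#' @export
dummyEncode <- function(labels, positiveClass) {
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) > 2L)
    stop("more than two classes; only two-class problems are supported")
  if (length(lev) < 2L)
    stop("degenerate response: only one class present")
  if (!positiveClass %in% lev)
    stop("positiveClass '", positiveClass, "' not found among the labels")
  as.numeric(labels == positiveClass)
}

# Default gamma search regions: a low region emphasizing variances and a
# high region emphasizing correlations.
.defaultGammaRegions <- function()
  list(lower = c(0.001, 0.050), upper = c(0.950, 0.999))

#' Powered loading weights
#'
#' Computes the CPPLS loading-weight vector for a centered predictor
#' residual matrix and a centered response residual. Element j is
#' `sign(corr_j) * |corr_j|^(gamma/(1-gamma)) * sd_j^((1-gamma)/gamma)`,
#' scaled to unit Euclidean length. Gamma near 1 emphasizes correlations,
#' gamma near 0 emphasizes standard deviations, and gamma = 0.5 gives the
#' classical PLS weight (proportional to the covariances). Computation is
#' done on the log scale so extreme exponents do not underflow.
#'
#' @param Xr column-centered residual predictor matrix (n x p).
#' @param yr centered residual response (length n).
#' @param gamma power parameter, strictly inside (0, 1).
#' @return unit-norm numeric p-vector. Columns with zero variance (or zero
#'   correlation) get weight 0.
#' @export
poweredLoadingWeights <- function(Xr, yr, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0 || gamma >= 1)
    stop("gamma must lie strictly inside (0, 1)")
  st <- .columnStats(Xr, yr)
  w <- .poweredWeightMatrix(st, gamma)[, 1L]
  nrm <- sqrt(sum(w^2))
  if (nrm == 0)
    stop("degenerate weights: no column has nonzero variance and correlation")
  w / nrm
}

# Column standard deviations and correlations with yr, computed once and
# reused across all gamma candidates. Zero-variance columns get corr 0.
.columnStats <- function(Xr, yr) {
  n <- nrow(Xr)
  ss <- colSums(Xr^2)
  if (all(ss == 0)) stop("all columns have zero variance")
  sdy <- sqrt(sum(yr^2))
  cv <- as.vector(crossprod(Xr, yr))
  corr <- ifelse(ss > 0 & sdy > 0, cv / (sqrt(ss) * sdy), 0)
  corr[abs(corr) > 1] <- sign(corr[abs(corr) > 1])   # guard rounding
  list(sd = sqrt(ss / max(n - 1L, 1L)), corr = corr)
}

# p x length(gammas) matrix of unnormalized powered weights (log-scale,
# shifted by the column max before exponentiation).
.poweredWeightMatrix <- function(st, gammas) {
  p <- length(st$corr)
  out <- matrix(0, p, length(gammas))
  ok <- abs(st$corr) > 0 & st$sd > 0
  if (!any(ok)) return(out)
  lc <- log(abs(st$corr[ok]))
  ls <- log(st$sd[ok])
  sg <- sign(st$corr[ok])
  for (i in seq_along(gammas)) {
    g <- gammas[i]
    lw <- (g / (1 - g)) * lc + ((1 - g) / g) * ls
    out[ok, i] <- sg * exp(lw - max(lw))
  }
  out
}

#' Select the power parameter gamma for one component
#'
#' Evaluates a grid of gamma candidates in the two search regions and
#' returns the one whose score vector t = Xr w(gamma) has maximal absolute
#' correlation with the response residual (for a single dummy response the
#' canonical correlation reduces to this). Ties go to the smaller gamma.
#'
#' @inheritParams poweredLoadingWeights
#' @param lowerRegion,upperRegion numeric length-2 intervals inside (0, 1).
#' @param gridSize number of equally spaced candidates per region.
#' @return the chosen gamma (numeric scalar).
#' @export
selectGamma <- function(Xr, yr,
                        lowerRegion = c(0.001, 0.050),
                        upperRegion = c(0.950, 0.999),
                        gridSize = 5L) {
  .gammaSearch(Xr, yr, lowerRegion, upperRegion, gridSize)$gamma
}

.gammaSearch <- function(Xr, yr, lowerRegion, upperRegion, gridSize) {
  if (gridSize < 1L) stop("empty candidate grid")
  cand <- sort(c(seq(lowerRegion[1], lowerRegion[2], length.out = gridSize),
                 seq(upperRegion[1], upperRegion[2], length.out = gridSize)))
  if (any(cand <= 0 | cand >= 1))
    stop("gamma regions must be sub-intervals of (0, 1)")
  st <- .columnStats(Xr, yr)
  Wc <- .poweredWeightMatrix(st, cand)
  nrm <- sqrt(colSums(Wc^2))
  if (all(nrm == 0))
    stop("degenerate weights: no column has nonzero variance and correlation")
  Wc <- sweep(Wc, 2L, pmax(nrm, .Machine$double.xmin), "/")
  Tc <- Xr %*% Wc
  score <- suppressWarnings(abs(as.vector(stats::cor(Tc, yr))))
  score[!is.finite(score) | nrm == 0] <- -Inf
  best <- which.max(score)            # candidates ascending: ties -> smaller
  list(gamma = cand[best], w = Wc[, best], score = score[best])
}

# Eq.-style coefficient vector from the first a components:
# beta_a = W_a (P1_a' W_a)^{-1} p2_a
.cpplsBeta <- function(W, P1, p2, a, ids = NULL) {
  Wa <- W[, seq_len(a), drop = FALSE]
  Pa <- P1[, seq_len(a), drop = FALSE]
  beta <- as.vector(Wa %*% solve(crossprod(Pa, Wa), p2[seq_len(a)]))
  if (!is.null(ids)) names(beta) <- ids
  beta
}

#' Fit a CPPLS regression on a two-class dataset
#'
#' Extracts up to `nComponents` latent components. For each component the
#' power parameter is chosen by [selectGamma()] on the current residuals,
#' the score is t = Xr w, loadings are p1 = Xr't/(t't) and p2 = yr't/(t't),
#' and both X and y residuals are deflated by the component. Predictors are
#' column-centered but not scaled (the powered weights already weigh in the
#' column standard deviations); the response is centered by its mean.
#' Extraction stops early, with a flag, if a score vector is numerically
#' zero (squared norm below `1e-12 * n`).
#'
#' @param data a [LabeledDataset-class].
#' @param nComponents maximum number of components k (k <= min(n-1, p)).
#' @param gammaRegions list with `lower` and `upper` length-2 intervals.
#' @param gridSize gamma candidates per region.
#' @return a [CpplsFit-class].
#' @examples
#' sim <- syntheticClassification(nPerClass = 15, p = 20, nInformative = 4,
#'                                delta = 2, seed = 1)
#' fit <- fitCppls(sim$data, nComponents = 2)
#' fit
#' @export
fitCppls <- function(data, nComponents = 1L,
                     gammaRegions = .defaultGammaRegions(),
                     gridSize = 5L) {
  stopifnot(is(data, "LabeledDataset"))
  X <- data@X
  n <- nrow(X); p <- ncol(X)
  k <- as.integer(nComponents)
  if (k < 1L) stop("nComponents must be >= 1")
  if (k > min(n - 1L, p))
    stop("nComponents must be <= min(n - 1, p)")
  xc <- colMeans(X)
  yc <- mean(data@y)
  Xr <- sweep(X, 2L, xc)
  yr <- data@y - yc
  W <- matrix(0, p, k); P1 <- matrix(0, p, k)
  Tm <- matrix(0, n, k); p2 <- numeric(k); gam <- numeric(k)
  degenerate <- FALSE
  a <- 0L
  while (a < k) {
    gs <- tryCatch(
      .gammaSearch(Xr, yr, gammaRegions$lower, gammaRegions$upper, gridSize),
      error = function(e) NULL)
    if (is.null(gs)) { degenerate <- TRUE; break }
    t <- as.vector(Xr %*% gs$w)
    tt <- sum(t^2)
    if (tt < 1e-12 * n) { degenerate <- TRUE; break }
    a <- a + 1L
    W[, a] <- gs$w
    Tm[, a] <- t
    P1[, a] <- as.vector(crossprod(Xr, t)) / tt
    p2[a] <- sum(yr * t) / tt
    gam[a] <- gs$gamma
    Xr <- Xr - tcrossprod(t, P1[, a])
    yr <- yr - t * p2[a]
  }
  if (a == 0L)
    stop("no component could be extracted (degenerate data)")
  keep <- seq_len(a)
  W <- W[, keep, drop = FALSE]; P1 <- P1[, keep, drop = FALSE]
  Tm <- Tm[, keep, drop = FALSE]
  ids <- colnames(X)
  new("CpplsFit",
      nComponents = a, W = W, P1 = P1, p2 = p2[keep], scores = Tm,
      gammas = gam[keep],
      beta = .cpplsBeta(W, P1, p2, a, ids),
      xCenter = xc, yCenter = yc, variableIds = ids,
      degenerate = degenerate)
}

#' Predict dummy values from a CPPLS fit
#'
#' Returns `(Xnew - xCenter) %*% beta_(a) + yCenter` where `beta_(a)` uses
#' the first `a` components. `a = 0` yields the constant `yCenter`.
#'
#' @param fit a [CpplsFit-class].
#' @param Xnew numeric matrix with the same columns as the training data.
#' @param a number of components (0 to `fit@nComponents`).
#' @return numeric vector of predicted dummy values.
#' @export
predictScores <- function(fit, Xnew, a = fit@nComponents) {
  Xnew <- as.matrix(Xnew)
  if (ncol(Xnew) != length(fit@xCenter))
    stop("Xnew must have ", length(fit@xCenter), " columns")
  a <- as.integer(a)
  if (a < 0L || a > fit@nComponents)
    stop("a must be between 0 and the number of fitted components")
  if (a == 0L) return(rep(fit@yCenter, nrow(Xnew)))
  beta <- .cpplsBeta(fit@W, fit@P1, fit@p2, a)
  as.vector(sweep(Xnew, 2L, fit@xCenter) %*% beta) + fit@yCenter
}

#' Train the 1-D LDA rule on predicted dummy values
#'
#' Gaussian class-conditional densities with pooled within-class variance
#' and class priors equal to the training frequencies.
#'
#' @param scoresTrain numeric vector of training predicted dummy values.
#' @param labelsTrain factor/vector of training class labels (two classes).
#' @return list with class means, pooled variance, priors and levels,
#'   consumed by [ldaClassify()].
#' @keywords internal
.ldaTrain <- function(scoresTrain, labelsTrain) {
  labelsTrain <- as.factor(as.character(labelsTrain))
  if (nlevels(labelsTrain) != 2L)
    stop("training labels must contain exactly two classes")
  lev <- levels(labelsTrain)
  mu <- tapply(scoresTrain, labelsTrain, mean)
  nK <- tabulate(labelsTrain, 2L)
  ssw <- sum((scoresTrain - mu[labelsTrain])^2)
  s2 <- ssw / max(length(scoresTrain) - 2L, 1L)
  if (s2 <= 0 && abs(mu[1] - mu[2]) < 1e-12)
    stop("degenerate LDA: zero pooled variance and overlapping class means")
  list(levels = lev, mu = as.vector(mu), s2 = s2,
       prior = nK / length(scoresTrain))
}

#' Classify by 1-D linear discriminant analysis on predicted dummies
#'
#' Trains the pooled-variance Gaussian rule on `(scoresTrain, labelsTrain)`
#' and classifies `scoresTest`. At a decision-boundary tie the class with
#' the larger prior wins; if priors tie too, the class with the larger
#' training mean score (the dummy-1 side) wins.
#'
#' @param scoresTrain,labelsTrain training predicted dummy values and class
#'   labels.
#' @param scoresTest predicted dummy values to classify.
#' @return character vector of predicted labels.
#' @examples
#' ldaClassify(c(0, 0.1, 0.9, 1), c("a", "a", "b", "b"), c(0.05, 0.95))
#' @export
ldaClassify <- function(scoresTrain, labelsTrain, scoresTest) {
  m <- .ldaTrain(scoresTrain, labelsTrain)
  .ldaPredict(m, scoresTest)
}

.ldaPredict <- function(m, scores) {
  if (m$s2 <= 0) {
    # perfectly separated training scores: nearest class mean
    d1 <- abs(scores - m$mu[1]); d2 <- abs(scores - m$mu[2])
    delta <- cbind(-d1, -d2)
  } else {
    delta <- vapply(1:2, function(k) {
      scores * m$mu[k] / m$s2 - m$mu[k]^2 / (2 * m$s2) + log(m$prior[k])
    }, numeric(length(scores)))
    delta <- matrix(delta, ncol = 2L)
  }
  pick <- integer(length(scores))
  for (i in seq_along(scores)) {
    if (delta[i, 1] > delta[i, 2]) pick[i] <- 1L
    else if (delta[i, 2] > delta[i, 1]) pick[i] <- 2L
    else if (m$prior[1] != m$prior[2]) pick[i] <- which.max(m$prior)
    else pick[i] <- which.max(m$mu)
  }
  m$levels[pick]
}
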