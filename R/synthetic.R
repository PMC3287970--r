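# Synthetic two-class data with a known sparse set of informative
# variables, used throughout the test suite in place of genome-scale data.

#' Generate a two-class dataset with known informative variables
#'
#' Draws a balanced two-class Gaussian dataset: `nInformative` columns
#' carry a class-mean shift of `delta` standard deviations (in units of
#' the column SD `noiseSd`) and, optionally, exchangeable correlation
#' `rho` within the informative block (generated exactly through a shared
#' standard-normal factor); all remaining columns are pure noise. The
#' informative columns are placed at random positions and their ids
#' returned as ground truth. Fully reproducible from `seed`.
#'
#' With `compositional = TRUE` each row is transformed to relative
#' frequencies (softmax over the row), mimicking frequency-type predictors
#' such as codon usage; the informative ids remain the shifted columns.
#'
#' @param nPerClass samples per class (total n = 2 * nPerClass).
#' @param p number of variables.
#' @param nInformative number of informative variables (<= p).
#' @param delta class-mean shift in SD units (>= 0; 0 gives null data).
#' @param rho exchangeable correlation within the informative block,
#'   in [0, 1).
#' @param noiseSd marginal standard deviation of every column.
#' @param seed integer seed; NULL leaves the RNG state alone.
#' @param compositional transform rows to relative frequencies.
#' @param positiveClass label used for the shifted-up class.
#' @return list with `data` (a [LabeledDataset-class]), `informative`
#'   (character ids of the informative variables) and `spec` (the
#'   generating parameters).
#' @examples
#' sim <- syntheticClassification(20, p = 50, nInformative = 5, delta = 2,
#'                                seed = 1)
#' sim$informative
#' @export
syntheticClassification <- function(nPerClass, p, nInformative, delta,
                                    rho = 0, noiseSd = 1, seed = NULL,
                                    compositional = FALSE,
                                    positiveClass = "case") {
  if (nInformative > p) stop("nInformative must be <= p")
  if (delta < 0) stop("delta must be >= 0")
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  if (nPerClass < 2L) stop("need at least 2 samples per class")
  if (!is.null(seed)) set.seed(seed)
  n <- 2L * nPerClass
  classes <- rep(c(positiveClass, "control"), each = nPerClass)
  X <- matrix(stats::rnorm(n * p, sd = noiseSd), n, p)
  info <- sort(sample.int(p, nInformative))
  if (nInformative > 0L) {
    if (rho > 0) {
      z <- stats::rnorm(n)
      eps <- matrix(stats::rnorm(n * nInformative), n, nInformative)
      X[, info] <- noiseSd * (sqrt(rho) * z + sqrt(1 - rho) * eps)
    }
    shift <- delta * noiseSd / 2
    X[classes == positiveClass, info] <-
      X[classes == positiveClass, info] + shift
    X[classes != positiveClass, info] <-
      X[classes != positiveClass, info] - shift
  }
  colnames(X) <- paste0("V", seq_len(p))
  rownames(X) <- paste0("S", seq_len(n))
  if (compositional) {
    X <- exp(X)
    X <- X / rowSums(X)
  }
  list(data = LabeledDataset(X, classes, positiveClass = positiveClass),
       informative = colnames(X)[info],
       spec = list(nPerClass = nPerClass, p = p,
                   nInformative = nInformative, delta = delta, rho = rho,
                   noiseSd = noiseSd, seed = seed,
                   compositional = compositional))
}
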