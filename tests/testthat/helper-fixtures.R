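# Shared fixture builders and independent oracles.

# Random continuous two-class dataset (no structure unless delta > 0).
randomDataset <- function(n, p, delta = 0, seed = 1) {
  sim <- syntheticClassification(nPerClass = n %/% 2L, p = p,
                                 nInformative = max(1L, p %/% 5L),
                                 delta = delta, seed = seed)
  sim$data
}

# Two well-separated Gaussian clusters (class signal in every variable).
separableDataset <- function(n = 40, p = 10, gap = 6, seed = 1) {
  set.seed(seed)
  half <- n %/% 2L
  X <- rbind(matrix(rnorm(half * p), half, p),
             matrix(rnorm(half * p, mean = gap), half, p))
  colnames(X) <- paste0("V", seq_len(p))
  LabeledDataset(X, rep(c("a", "b"), each = half), positiveClass = "b")
}

# Brute-force one-sided binomial tail by enumeration (oracle for the
# exact McNemar p-value).
bruteBinomTail <- function(b, n) {
  if (n == 0L) return(1)
  sum(choose(n, 0:b)) / 2^n
}

# Build a CorrectnessRecord directly from a 0/1 matrix.
makeRecord <- function(correct) {
  correct <- as.matrix(correct)
  new("CorrectnessRecord", correct = correct, P = colMeans(correct),
      scheme = "loo", foldAssignment = seq_len(nrow(correct)),
      foldBetas = list())
}

# Build a minimal valid CpplsFit with given unit-normalized weights.
makeFit <- function(W, p2 = rep(1, ncol(W)), scores = NULL,
                    P1 = NULL, ids = NULL) {
  W <- as.matrix(W)
  W <- sweep(W, 2L, sqrt(colSums(W^2)), "/")
  p <- nrow(W); k <- ncol(W)
  if (is.null(scores)) scores <- matrix(seq_len(6L * k), 6L, k)
  if (is.null(P1)) P1 <- W
  if (is.null(ids)) ids <- paste0("V", seq_len(p))
  new("CpplsFit", nComponents = as.integer(k), W = W, P1 = P1,
      p2 = as.numeric(p2), scores = as.matrix(scores),
      gammas = rep(0.5, k), beta = rep(0, p), xCenter = rep(0, p),
      yCenter = 0.5, variableIds = ids, degenerate = FALSE)
}

# Build an EliminationTrace directly from per-iteration correctness
# vectors and retained-variable counts.
makeTrace <- function(correctList, sizes, ids = NULL) {
  p <- sizes[1L]
  if (is.null(ids)) ids <- paste0("V", seq_len(p))
  its <- lapply(seq_along(sizes), function(g) {
    list(retained = ids[seq_len(sizes[g])],
         P = mean(correctList[[g]]),
         correct = as.integer(correctList[[g]]),
         aHat = 1L, cLevel = 0.5, M = 0L, N = 0L)
  })
  new("EliminationTrace", iterations = its, variableIds = ids,
      criterion = "vip")
}

# Term-by-term VIP evaluation, written directly from the definition,
# independent of criterionVip's vectorized path.
bruteVip <- function(fit, aHat) {
  W <- loadingWeights(fit); Tm <- componentScores(fit)
  p2 <- yLoadings(fit); p <- nrow(W)
  num <- numeric(p); den <- 0
  for (a in seq_len(aHat)) {
    expl <- p2[a]^2 * sum(Tm[, a]^2)
    den <- den + expl
    for (j in seq_len(p))
      num[j] <- num[j] + expl * (W[j, a] / sqrt(sum(W[, a]^2)))^2
  }
  sqrt(p * num / den)
}

# A tiny two-genome CDS FASTA pair written to tempfiles.
toyGenomeFastas <- function() {
  d <- withr::local_tempdir(.local_envir = parent.frame())
  g1 <- file.path(d, "g1.fasta")
  writeLines(c(">gene1", "ATGAAATTT", ">gene2", "ATGGGG"), g1)
  g2 <- file.path(d, "g2.fasta")
  writeLines(c(">gene1", "ATGCCCAAA"), g2)
  c(g1 = g1, g2 = g2)
}
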