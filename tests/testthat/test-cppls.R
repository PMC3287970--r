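# CPPLS core: dummy coding, powered weights, gamma search, fitting,
# prediction and the 1-D LDA rule.

test_that("dummy coding maps the positive class to 1 and rejects degenerate input", {
  expect_equal(dummyEncode(c("A", "B", "A"), "A"), c(1, 0, 1))
  expect_equal(dummyEncode(c("notX", "X", "X", "notX"), "X"), c(0, 1, 1, 0))
  expect_error(dummyEncode(c("A", "A", "A"), "A"), "degenerate")
  expect_error(dummyEncode(c("A", "B", "C"), "A"), "two-class")
  expect_error(dummyEncode(c("A", "B"), "Z"), "not found")
})

test_that("powered weights are unit-norm and reduce to covariances at gamma 0.5", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(10:40, 1); p <- sample(2:30, 1)
    Xr <- scale(matrix(rnorm(n * p), n, p), scale = FALSE)
    yr <- rnorm(n); yr <- yr - mean(yr)
    w <- poweredLoadingWeights(Xr, yr, 0.5)
    expect_lt(abs(sqrt(sum(w^2)) - 1), 1e-12)
    cv <- as.vector(crossprod(Xr, yr))          # oracle: plain covariances
    expect_lt(max(abs(w - cv / sqrt(sum(cv^2)))), 1e-10)
  }
})

test_that("gamma near 1 concentrates weight on the high-correlation variable", {
  set.seed(42)
  n <- 400
  yr <- rnorm(n); yr <- yr - mean(yr)
  x1 <- 0.9 * yr + sqrt(1 - 0.81) * rnorm(n) * sd(yr)
  x2 <- 0.3 * yr + sqrt(1 - 0.09) * rnorm(n) * sd(yr)
  Xr <- scale(cbind(x1, x2), scale = FALSE)
  # equalize the empirical standard deviations exactly
  Xr <- sweep(Xr, 2L, apply(Xr, 2L, sd), "/")
  w <- poweredLoadingWeights(Xr, yr, 0.999)
  expect_gt(abs(w[1]), 0.99)
})

test_that("powered weights validate gamma and zero-variance input", {
  Xr <- scale(matrix(rnorm(30), 10, 3), scale = FALSE)
  yr <- rnorm(10); yr <- yr - mean(yr)
  expect_error(poweredLoadingWeights(Xr, yr, 0), "gamma")
  expect_error(poweredLoadingWeights(Xr, yr, 1), "gamma")
  expect_error(poweredLoadingWeights(matrix(0, 10, 3), yr, 0.5),
               "zero variance")
  # zero-variance column gets weight exactly 0
  Xr0 <- cbind(Xr, 0)
  expect_identical(poweredLoadingWeights(Xr0, yr, 0.3)[4], 0)
})

test_that("gamma selection maximizes |cor(t, yr)| and breaks ties downward", {
  # single variable: every gamma gives the same +/- unit weight, so all
  # scores tie and the smallest candidate must be returned
  set.seed(1)
  Xr <- matrix(rnorm(20), 20, 1); Xr <- Xr - mean(Xr)
  yr <- rnorm(20); yr <- yr - mean(yr)
  expect_equal(selectGamma(Xr, yr), 0.001)

  # one variable carries all the class signal, the rest are high-variance
  # noise: the correlation-emphasizing upper region must win; verify
  # against exhaustive evaluation of the same grid
  set.seed(2)
  n <- 60
  yr <- rep(c(-0.5, 0.5), each = n / 2)
  signal <- yr + 0.1 * rnorm(n)
  noise <- matrix(rnorm(n * 5, sd = 20), n, 5)
  Xr <- scale(cbind(signal, noise), scale = FALSE)
  g <- selectGamma(Xr, yr)
  expect_gte(g, 0.95)
  grid <- c(seq(0.001, 0.05, length.out = 5), seq(0.95, 0.999, length.out = 5))
  scores <- vapply(grid, function(gg) {
    abs(cor(as.vector(Xr %*% poweredLoadingWeights(Xr, yr, gg)), yr))
  }, 1.0)
  expect_equal(g, grid[which.max(scores)])
})

test_that("a one-component fit has beta proportional to the loading weights", {
  d <- randomDataset(20, 8, delta = 1, seed = 3)
  fit <- fitCppls(d, 1)
  w <- loadingWeights(fit)[, 1]
  beta <- coefficients(fit)
  ratio <- beta[w != 0] / w[w != 0]
  expect_lt(diff(range(ratio)), 1e-10 * max(abs(ratio)))
})

test_that("with k = p components on well-conditioned data CPPLS matches OLS", {
  set.seed(4)
  n <- 30; p <- 5
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("V", 1:p)
  cl <- rep(c("a", "b"), each = n / 2)
  d <- LabeledDataset(X, cl, positiveClass = "b")
  fit <- fitCppls(d, p)
  ols <- lm.fit(cbind(1, X), dummyResponse(d))
  pred <- predictScores(fit, X)
  expect_lt(max(abs(pred - ols$fitted.values)), 1e-6)
})

test_that("noiseless linear response is reproduced exactly at full rank", {
  set.seed(5)
  n <- 24; p <- 6
  X <- matrix(rnorm(n * p), n, p)
  beta <- rnorm(p)
  yq <- X %*% beta
  cl <- ifelse(yq > median(yq), "hi", "lo")
  d0 <- LabeledDataset(X, cl, positiveClass = "hi")
  # replace the dummy by a noiseless linear response through the fit path:
  # predictions at k = p must match OLS on the same 0/1 response to 1e-8
  fit <- fitCppls(d0, p)
  ols <- lm.fit(cbind(1, X), dummyResponse(d0))
  expect_lt(max(abs(predictScores(fit, X) - ols$fitted.values)), 1e-8)
})

test_that("a constant column gets zero weight and zero coefficient", {
  d <- randomDataset(20, 5, delta = 2, seed = 6)
  X <- cbind(predictorMatrix(d), konst = 7)
  d2 <- LabeledDataset(X, classLabels(d), positiveClass = positiveClass(d))
  fit <- fitCppls(d2, 2)
  expect_true(all(loadingWeights(fit)[6, ] == 0))
  expect_lt(abs(coefficients(fit)[6]), 1e-12)
})

test_that("score vectors are mutually orthogonal and Eq-style beta matches accumulation", {
  for (seed in 1:5) {
    d <- randomDataset(30, 12, delta = 1, seed = seed)
    fit <- fitCppls(d, 4)
    Tm <- componentScores(fit)
    G <- crossprod(Tm)
    offdiag <- abs(G[upper.tri(G)]) / sqrt(diag(G)[1])
    expect_lt(max(offdiag), 1e-8)
    # accumulated per-component regressions vs the coefficient form
    acc <- fit@yCenter + as.vector(Tm %*% yLoadings(fit))
    expect_lt(max(abs(acc - predictScores(fit, predictorMatrix(d)))), 1e-8)
  }
})

test_that("predictScores validates input and handles the empty model", {
  d <- randomDataset(16, 6, delta = 1, seed = 7)
  fit <- fitCppls(d, 2)
  X <- predictorMatrix(d)
  expect_error(predictScores(fit, X[, 1:3]), "columns")
  expect_equal(predictScores(fit, X, a = 0), rep(fit@yCenter, nrow(X)))
  # duplicated row yields an identical prediction
  p2 <- predictScores(fit, X[c(1, 1), ])
  expect_identical(p2[1], p2[2])
})

test_that("the LDA rule classifies by pooled-variance discriminants with tie rules", {
  tr <- c(-0.1, 0.1, 0.9, 1.1)
  lab <- c("c0", "c0", "c1", "c1")
  expect_equal(ldaClassify(tr, lab, 0.95), "c1")
  expect_equal(ldaClassify(tr, lab, 0.02), "c0")
  # equal priors: boundary is the midpoint of the class means; just below
  # it the smaller-mean class wins, exactly at it the larger-mean class
  mid <- 0.5
  expect_equal(ldaClassify(tr, lab, mid - 1e-9), "c0")
  expect_equal(ldaClassify(tr, lab, mid), "c1")
  # unequal priors shift the boundary toward the rarer class
  expect_equal(ldaClassify(c(-0.1, 0.1, 0.3, 1), c("c0", "c0", "c0", "c1"),
                           0.55), "c0")
  # degenerate: zero pooled variance with overlapping means
  expect_error(ldaClassify(c(0.5, 0.5, 0.5, 0.5), lab, 0.5), "degenerate")
  # zero variance but separated means: nearest-mean rule
  expect_equal(ldaClassify(c(0, 0, 1, 1), lab, 0.9), "c1")
})
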