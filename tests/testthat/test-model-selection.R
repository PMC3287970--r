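# Cross-validation records, the exact McNemar test, and the first
# (dimension) regularization.

test_that("LOO cross-validation is perfect on well-separated clusters", {
  d <- separableDataset(n = 40, p = 10, gap = 6, seed = 1)
  rec <- crossValidate(d, maxComponents = 2)
  expect_equal(unname(rec@P[1]), 1.0)
})

test_that("cross-validated performance is near 1/2 on permuted labels", {
  perfs <- vapply(1:8, function(seed) {
    sim <- syntheticClassification(20, p = 10, nInformative = 2, delta = 0,
                                   seed = seed)
    mean(crossValidate(sim$data, maxComponents = 2)@P)
  }, 1.0)
  # 3 binomial SEs around 0.5 for 8 x 40 held-out classifications
  se <- sqrt(0.25 / (8 * 40))
  expect_lt(abs(mean(perfs) - 0.5), 3 * se + 0.02)
})

test_that("duplicated samples make LOO equivalent to seen-data evaluation", {
  d <- separableDataset(n = 20, p = 6, gap = 6, seed = 2)
  X2 <- rbind(predictorMatrix(d), predictorMatrix(d))
  rownames(X2) <- paste0("S", seq_len(nrow(X2)))
  d2 <- LabeledDataset(X2, rep(as.character(classLabels(d)), 2),
                       positiveClass = positiveClass(d))
  rec <- crossValidate(d2, maxComponents = 1)
  expect_equal(unname(rec@P[1]), 1.0)
})

test_that("k-fold folds are stratified and the record exposes fold betas", {
  d <- randomDataset(30, 8, delta = 1, seed = 3)
  rec <- crossValidate(d, maxComponents = 2, scheme = "kfold", folds = 5,
                       seed = 1)
  expect_equal(length(rec@foldBetas), 5L)
  expect_equal(dim(rec@foldBetas[[1]]), c(8L, 2L))
  cls <- classLabels(d)
  for (f in 1:5)
    expect_equal(nlevels(droplevels(cls[rec@foldAssignment != f])), 2L)
})

test_that("the exact McNemar p-value matches its definition", {
  expect_equal(mcnemarPvalue(c(1, 0, 1), c(1, 0, 1)), 1)       # identical
  cand <- c(rep(0, 10), rep(1, 5)); ref <- rep(1, 15)          # b=0, c=10
  expect_equal(mcnemarPvalue(cand, ref), 2^-10)
  cand <- c(rep(1, 5), rep(0, 5)); ref <- c(rep(0, 5), rep(1, 5))  # b=c=5
  expect_equal(mcnemarPvalue(cand, ref), bruteBinomTail(5, 10))
  expect_error(mcnemarPvalue(c(1, 0), c(1, 0, 1)), "length")
})

test_that("McNemar ignores samples where both models agree", {
  set.seed(4)
  a <- rbinom(30, 1, 0.7); b <- rbinom(30, 1, 0.7)
  base <- mcnemarPvalue(a, b)
  expect_equal(mcnemarPvalue(c(a, 1, 0), c(b, 1, 0)), base)
})

test_that("dimension estimation applies the first regularization", {
  # identical correctness columns tie at the max: the smallest tied a is
  # both aStar and (p = 1 against itself) aHat, at any c
  col <- c(rep(1, 25), rep(0, 5))
  worse <- c(rep(1, 20), rep(0, 10))
  rec <- makeRecord(cbind(col, col, worse))    # P: .83 .83 .67
  est <- estimateDimension(rec, 0.5)
  expect_equal(est$aStar, 1L)
  expect_equal(est$aHat, 1L)

  # constructed discordance: a=1 vs a*=3 has b=0,c=10; a=2 vs a*=3 has
  # b=4,c=5 -> at c=0.05 the estimate is 2
  a3 <- c(rep(1, 24), rep(0, 6))
  a1 <- a3; a1[1:10] <- 0
  a2 <- a3; a2[1:5] <- 0; a2[25:28] <- 1
  rec <- makeRecord(cbind(a1, a2, a3))
  expect_equal(unname(which.max(rec@P)), 3L)
  est <- estimateDimension(rec, 0.05)
  expect_equal(est$aStar, 3L)
  expect_equal(est$aHat, 2L)
  expect_equal(est$pValues[1], 2^-10)
  expect_equal(est$pValues[2], bruteBinomTail(4, 9))
})

test_that("aHat never exceeds aStar and shrinks as c decreases", {
  set.seed(5)
  for (rep in 1:20) {
    rec <- makeRecord(matrix(rbinom(40 * 4, 1, 0.8), 40, 4))
    prev <- Inf
    for (cl in c(1, 0.5, 0.1, 0.01)) {
      est <- estimateDimension(rec, cl)
      expect_lte(est$aHat, est$aStar)
      expect_lte(est$aHat, prev)
      prev <- est$aHat
    }
  }
})
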