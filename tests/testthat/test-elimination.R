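# The regularized backward-elimination loop, the second regularization,
# and f/d tuning.

test_that("each iteration eliminates N = ceiling(f * M) flagged variables", {
  sim <- syntheticClassification(12, p = 40, nInformative = 5, delta = 2,
                                 seed = 1)
  tr <- eliminate(sim$data, "vip", f = 0.3, cLevel = 0.5, maxComponents = 2)
  df <- as.data.frame(tr)
  active <- df$M > 0 & df$N > 0
  expect_true(all(df$N[active] == pmin(ceiling(0.3 * df$M[active]),
                                       df$nVariables[active] - 1L)))
  expect_true(all(diff(df$nVariables) < 0))
  expect_true(all(df$nVariables - c(df$nVariables[-1], NA) == df$N,
                  na.rm = TRUE))
})

test_that("no flagged variable means a single-iteration trace", {
  sim <- syntheticClassification(10, p = 8, nInformative = 3, delta = 2,
                                 seed = 2)
  # loading criterion with u = 0: nothing is strictly below 0
  tr <- eliminate(sim$data, "loading", u = 0, f = 0.5, cLevel = 0.5,
                  maxComponents = 2)
  expect_equal(length(tr@iterations), 1L)
  expect_equal(as.data.frame(tr)$M, 0L)
  expect_equal(retainedVariables(tr, 0), variableIds(sim$data))
})

test_that("the last variable is never eliminated", {
  sim <- syntheticClassification(10, p = 12, nInformative = 3, delta = 3,
                                 seed = 3)
  # f = 1 with the permissive VIP cutoff tries to flag everything
  tr <- eliminate(sim$data, "vip", f = 1, cLevel = 0.5, maxComponents = 2)
  df <- as.data.frame(tr)
  expect_true(all(df$nVariables - df$N >= 1L))
})

test_that("the elimination trace is deterministic", {
  sim <- syntheticClassification(12, p = 30, nInformative = 4, delta = 2,
                                 seed = 4)
  tr1 <- eliminate(sim$data, "vip", f = 0.5, cLevel = 0.5, maxComponents = 2)
  tr2 <- eliminate(sim$data, "vip", f = 0.5, cLevel = 0.5, maxComponents = 2)
  expect_identical(as.data.frame(tr1), as.data.frame(tr2))
  expect_identical(tr1@iterations, tr2@iterations)
})

test_that("the qvalue criterion drives elimination too", {
  sim <- syntheticClassification(14, p = 25, nInformative = 4, delta = 2.5,
                                 seed = 5)
  tr <- eliminate(sim$data, "qvalue", f = 0.5, cLevel = 0.5,
                  maxComponents = 2)
  expect_gt(length(tr@iterations), 1L)
  fin <- chooseFinalIteration(tr, 0.99)
  expect_gte(fin$gFinal, fin$gStar)
})

test_that("the second regularization picks the largest not-worse iteration", {
  # all iterations identical in correctness: final = last (fewest vars)
  base <- c(rep(1L, 25), rep(0L, 5))
  tr <- makeTrace(list(base, base, base), sizes = c(20L, 10L, 4L))
  fin <- chooseFinalIteration(tr, 0.5)
  expect_equal(fin$gStar, 3L)     # largest g on ties
  expect_equal(fin$gFinal, 3L)
  expect_true(all(fin$pValues == 1))

  # constructed discordance beyond g*: g*+1 has b=4,c=5 (p ~ 0.5), g*+2
  # has b=0,c=10 (p ~ 0.001): at d = 0.05 the final iteration is g*+1
  g0 <- c(rep(1L, 24), rep(0L, 6))
  g1 <- g0; g1[1:5] <- 0L; g1[25:28] <- 1L
  g2 <- g0; g2[1:10] <- 0L
  tr <- makeTrace(list(g0, g1, g2), sizes = c(30L, 12L, 5L))
  fin <- chooseFinalIteration(tr, 0.05)
  expect_equal(fin$gStar, 1L)
  expect_equal(fin$gFinal, 2L)
  expect_equal(unname(fin$pValues), c(1, bruteBinomTail(4, 9), 2^-10))
  expect_equal(fin$selected, paste0("V", 1:12))

  # d = 1 keeps only iterations with p = 1 (identical correctness)
  expect_equal(chooseFinalIteration(tr, 1)$gFinal, 1L)
})

test_that("gFinal is nonincreasing and model size nondecreasing in d", {
  set.seed(6)
  for (rep in 1:10) {
    n <- 30
    cols <- lapply(1:5, function(i) rbinom(n, 1, 0.8))
    tr <- makeTrace(cols, sizes = c(50L, 30L, 18L, 9L, 4L))
    prevG <- Inf; prevSize <- -Inf
    for (d in c(0.01, 0.2, 0.6, 0.99)) {
      fin <- chooseFinalIteration(tr, d)
      expect_gte(fin$gFinal, fin$gStar)
      expect_lte(fin$gFinal, prevG)
      expect_gte(length(fin$selected), prevSize)
      prevG <- fin$gFinal; prevSize <- length(fin$selected)
    }
  }
})

test_that("singleton grids make tuneAndSelect equal eliminate + final choice", {
  sim <- syntheticClassification(12, p = 20, nInformative = 4, delta = 2.5,
                                 seed = 7)
  res <- tuneAndSelect(sim$data, "vip", fGrid = 0.5, dGrid = 0.5,
                       cGrid = 0.5, maxComponents = 2)
  tr <- eliminate(sim$data, "vip", f = 0.5, cLevel = 0.5, maxComponents = 2)
  fin <- chooseFinalIteration(tr, 0.5)
  expect_identical(selectedVariables(res), fin$selected)
  expect_identical(as.data.frame(res@trace), as.data.frame(tr))
})

test_that("smaller d never selects more variables than larger d", {
  sim <- syntheticClassification(15, p = 40, nInformative = 6, delta = 2,
                                 seed = 8)
  r1 <- tuneAndSelect(sim$data, "vip", fGrid = 0.5, dGrid = 0.01,
                      cGrid = 0.5, maxComponents = 2)
  r2 <- tuneAndSelect(sim$data, "vip", fGrid = 0.5, dGrid = 0.99,
                      cGrid = 0.5, maxComponents = 2)
  expect_lte(length(selectedVariables(r1)), length(selectedVariables(r2)))
})

test_that("grid tuning runs end to end and returns a usable classifier", {
  sim <- syntheticClassification(12, p = 15, nInformative = 4, delta = 3,
                                 seed = 9)
  res <- tuneAndSelect(sim$data, "vip", fGrid = c(0.5, 1), dGrid = c(0.01, 0.99),
                       cGrid = 0.5, maxComponents = 2, folds = 4, seed = 1)
  expect_true(res@f %in% c(0.5, 1))
  expect_true(res@d %in% c(0.01, 0.99))
  pred <- predict(res, predictorMatrix(sim$data))
  expect_gt(mean(pred == as.character(classLabels(sim$data))), 0.9)
})
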