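test_that("mean well fluorescence is the plain region mean", {
  expect_equal(meanWellFluorescence(matrix(7, 5, 5)), 7)
  cb <- matrix(c(0, 10), 4, 4)
  expect_equal(meanWellFluorescence(cb), 5)
  expect_error(meanWellFluorescence(matrix(1, 2, 2),
                                    mask = matrix(FALSE, 2, 2)), "empty")
  # synthetic noisy well recovered within 3 sigma / sqrt(N)
  set.seed(41)
  img <- matrix(rnorm(200 * 200, mean = 120, sd = 8), 200)
  expect_lt(abs(meanWellFluorescence(img) - 120), 3 * 8 / sqrt(200 * 200))
})

test_that("plateau detection finds the largest flat terminal run", {
  mk <- function(means) TitrationSeries(seq_along(means),
                                        matrix(means, ncol = 1))
  # worked ladder: only the last two are mutually within 2 %
  s <- mk(c(1.00, 1.00, 1.10, 1.30, 1.45, 1.47, 1.48))
  expect_equal(detectPlateau(s, relTol = 0.02), c(6, 7))
  # constant means: the whole ladder is a plateau
  expect_equal(detectPlateau(mk(rep(2, 5)), 0.02), 1:5)
  # strictly increasing 10 % steps: no plateau
  expect_length(detectPlateau(mk(1.1 ^ (0:5)), 0.02), 0)
  expect_error(detectPlateau(mk(c(1, 2))), "at least 3")
})

test_that("fold change at saturation matches its arithmetic", {
  fl <- rbind(rep(100, 5), rep(120, 5), rep(147.5, 5), rep(147.5, 5))
  s <- TitrationSeries(c(0, 54, 108, 216), fl)
  fc <- foldChangeAtSaturation(s, c(108, 216))
  expect_equal(fc$fold, 1.475)
  expect_equal(fc$percentIncrease, 47.5)
  expect_equal(fc$median, 1.475)
  expect_equal(fc$n, 10)
  # plateau at baseline level: fold 1, +0 %
  s0 <- TitrationSeries(c(0, 10, 20), matrix(100, 3, 4))
  fc0 <- foldChangeAtSaturation(s0, c(10, 20))
  expect_equal(fc0$fold, 1)
  expect_equal(fc0$percentIncrease, 0)
  expect_error(foldChangeAtSaturation(s, numeric(0)), "empty")
  sneg <- new("TitrationSeries", binderNM = c(1, 2),
              fluorescence = matrix(1, 2, 2), baseline = 0)
  expect_error(foldChangeAtSaturation(sneg, 2), "baseline")
})

test_that("fold change is scale invariant", {
  ts <- generateTitration(noiseCV = 0.05, seed = 5L)
  pl <- detectPlateau(ts, relTol = 0.05)
  if (length(pl) == 0) pl <- c(108, 216)
  f1 <- foldChangeAtSaturation(ts, pl)
  scaled <- TitrationSeries(ts@binderNM, ts@fluorescence * 37.2)
  f2 <- foldChangeAtSaturation(scaled, pl)
  expect_equal(f1$fold, f2$fold, tolerance = 1e-12)
  expect_equal(f1$median, f2$median, tolerance = 1e-12)
})

test_that("noisy synthetic titrations recover the true fold", {
  ts <- generateTitration(trueF = 1.475, noiseCV = 0.05, replicates = 5,
                          seed = 8L)
  pl <- detectPlateau(ts, relTol = 0.05)
  expect_gte(length(pl), 2)
  fc <- foldChangeAtSaturation(ts, pl)
  ci <- 1.96 * fc$sd / sqrt(fc$n)
  expect_lt(abs(fc$fold - 1.475), ci + 0.02)
})

test_that("estimator bias is small across true folds", {
  for (f in c(1.0, 1.2, 1.475, 2.0)) {
    est <- vapply(1:40, function(s) {
      ts <- generateTitration(trueF = f, noiseCV = 0.04, replicates = 5,
                              seed = 1000L + s)
      foldChangeAtSaturation(ts, c(108, 216))$fold
    }, 0)
    expect_lt(abs(mean(est) - f), 0.04 / sqrt(5 * 2))
  }
})

test_that("per-concentration significance uses the requested variance model", {
  ts <- generateTitration(trueF = 1.475, noiseCV = 0.03, replicates = 5,
                          seed = 12L)
  sigEq <- titrationSignificance(ts, varEqual = TRUE)
  sigW <- titrationSignificance(ts, varEqual = FALSE)
  # saturating concentrations are clearly significant
  expect_true(all(sigEq$p[sigEq$conc_nM >= 108] < 0.0005))
  # equal-variance df is n1 + n2 - 2; Welch df differs in general
  expect_true(all(sigEq$df == 8))
  expect_false(all(sigW$df == 8))
})

test_that("linearity checks flag proportional measurements", {
  concs <- c(43.5, 54.4, 72.5, 108.8)
  exact <- suppressWarnings(linearityCheck(concs, 2 * concs))
  expect_equal(exact$slope, 2, tolerance = 1e-12)
  expect_equal(exact$intercept, 0, tolerance = 1e-9)
  expect_equal(exact$r2, 1, tolerance = 1e-12)
  expect_true(exact$proportional)
  # constant response: R's lm warns about the zero-residual fit
  flat <- suppressWarnings(linearityCheck(concs, rep(5, 4)))
  expect_equal(flat$r2, 0)
  expect_false(flat$proportional)
  # 2 % noise keeps R^2 above the linear-range threshold in most draws
  set.seed(3)
  hits <- vapply(1:50, function(i) {
    m <- 2 * concs * (1 + rnorm(4, sd = 0.02))
    linearityCheck(concs, m)$r2 > 0.98
  }, NA)
  expect_gt(mean(hits), 0.8)
  expect_error(linearityCheck(c(1, 2), c(1, 2)), ">= 3")
  expect_error(linearityCheck(rep(3, 4), 1:4), "zero variance")
})
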