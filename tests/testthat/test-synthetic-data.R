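test_that("noiseless, unbound bundles reproduce the ground truth exactly", {
  p <- smallScene(noiseSD = 0, seed = 1L)
  b <- generateProfileBundle(p)
  expect_identical(intensities(b$profiles$GFP), b$groundTruth@targetTrue)
  expect_identical(b$groundTruth@observed, b$groundTruth@targetTrue)
  expect_identical(positions(b$profiles$GFP), b$groundTruth@x)
})

test_that("full occupancy enhances a uniform target by exactly F", {
  p <- smallScene(noiseSD = 0, enhancementFactor = 1.475,
                  boundFraction = function(x) rep(1, length(x)),
                  targetMix = c(0, 0, 0, 1), seed = 1L)
  b <- generateProfileBundle(p)
  expect_equal(b$groundTruth@observed, 1.475 * b$groundTruth@targetTrue,
               tolerance = 1e-12)
  # a constant true intensity of 100 observes as 147.5
  flat <- b$groundTruth@x > p@lumenExtentUm + 2 &
          b$groundTruth@x < p@junctionPosUm - 2
  expect_true(any(flat))
  expect_equal(unique(round(b$groundTruth@observed[flat] /
                            b$groundTruth@targetTrue[flat], 9)), 1.475)
})

test_that("bundles are bit-identical for identical seed and params", {
  p <- smallScene(noiseSD = 3, shotNoise = TRUE, seed = 42L)
  b1 <- generateProfileBundle(p)
  b2 <- generateProfileBundle(p)
  expect_identical(lapply(b1$profiles, intensities),
                   lapply(b2$profiles, intensities))
  s1 <- generateCrossSection(p, widthUm = 8)
  s2 <- generateCrossSection(p, widthUm = 8)
  expect_identical(s1@channels, s2@channels)
  b3 <- generateProfileBundle(smallScene(noiseSD = 3, shotNoise = TRUE,
                                         seed = 43L))
  expect_false(identical(intensities(b1$profiles$GFP),
                         intensities(b3$profiles$GFP)))
})

test_that("observed intensity is pointwise monotone in the bound fraction", {
  levels <- c(0, 0.25, 0.5, 0.75, 1)
  prev <- NULL
  for (b in levels) {
    p <- smallScene(noiseSD = 0, seed = 1L,
                    boundFraction = local({bb <- b
                      function(x) rep(bb, length(x))}))
    obs <- generateProfileBundle(p)$groundTruth@observed
    if (!is.null(prev)) expect_true(all(obs >= prev - 1e-12))
    prev <- obs
  }
})

test_that("the junctional marker has a unique global max at the junction", {
  for (jpos in c(10, 12, 15)) {
    p <- smallScene(junctionPosUm = jpos, noiseSD = 0, seed = 1L)
    dlg <- generateProfileBundle(p)$profiles$Dlg
    i <- which(intensities(dlg) == max(intensities(dlg)))
    expect_length(i, 1)
    expect_lt(abs(positions(dlg)[i] - jpos), p@pixelUm)
  }
})

test_that("column-averaging a section reproduces the bundle profile", {
  p0 <- smallScene(noiseSD = 0, seed = 1L)
  sec0 <- generateCrossSection(p0, widthUm = 8)
  prof0 <- generateProfileBundle(p0)$profiles$GFP
  expect_equal(rowMeans(sec0@channels$GFP), intensities(prof0),
               tolerance = 1e-12)
  # width-1 section: the single column IS the profile
  sec1 <- generateCrossSection(p0, widthUm = p0@pixelUm)
  expect_equal(ncol(sec1@channels$GFP), 1)
  expect_equal(as.numeric(sec1@channels$GFP), intensities(prof0))
  # noisy: pointwise within 3 * sd / sqrt(width)
  pN <- smallScene(noiseSD = 4, seed = 9L)
  w <- round(8 / pN@pixelUm)
  secN <- generateCrossSection(pN, widthUm = 8)
  truth <- apicobasal:::.sceneTruth(pN)@observed
  dev <- abs(rowMeans(secN@channels$GFP) - truth)
  expect_lt(mean(dev > 3 * 4 / sqrt(w)), 0.01)
})

test_that("invalid scene parameters are rejected", {
  expect_error(smallScene(pixelUm = -1), "pixelUm")
  expect_error(smallScene(targetMix = c(0, 0, 0, 0)), "targetMix")
  expect_error(smallScene(junctionPosUm = 2), "junctionPosUm")
  expect_error(smallScene(enhancementFactor = 0.9), "enhancementFactor")
  expect_error(smallScene(boundFraction = function(x) x * 10),
               "boundFraction")
  expect_error(smallScene(trapCompartment = "nowhere"), "trapCompartment")
})

test_that("titration generator follows tight-binding occupancy", {
  # binder at 2x target: occupancy 1, fold exactly trueF
  ts <- generateTitration(trueF = 1.475, gfpNM = 54,
                          binderNM = c(0, 108), replicates = 3,
                          noiseCV = 0, seed = 1L)
  expect_equal(unique(as.vector(ts@fluorescence[2, ] / ts@baseline)), 1.475)
  # binder at half the target: fold = 1 + 0.475 * 0.5
  ts2 <- generateTitration(trueF = 1.475, gfpNM = 54,
                           binderNM = c(0, 27), replicates = 2,
                           noiseCV = 0, seed = 1L)
  expect_equal(unique(as.vector(ts2@fluorescence[2, ] / ts2@baseline)),
               1.2375)
  # no binder, no change
  expect_equal(mean(ts@fluorescence[1, ]) / ts@baseline, 1.0)
  # seeded determinism
  a <- generateTitration(noiseCV = 0.05, seed = 7L)
  b <- generateTitration(noiseCV = 0.05, seed = 7L)
  expect_identical(a@fluorescence, b@fluorescence)
})

test_that("titration generator validates its inputs", {
  expect_error(generateTitration(trueF = 0.5), "trueF")
  expect_error(generateTitration(binderNM = c(10, 5)), "increasing")
  expect_error(generateTitration(replicates = 0), "replicates")
})
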