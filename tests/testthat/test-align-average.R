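test_that("junction peak detection handles maxima, plateaus and noise", {
  # unique maximum
  p <- IntensityProfile(c(0, 0.5, 1, 1.5, 2), c(0, 1, 5, 2, 1))
  expect_equal(detectJunctionPeak(p), 1.0)
  # tied plateau: centroid
  p2 <- IntensityProfile(c(0, 0.5, 1, 1.5, 2), c(0, 5, 5, 2, 1))
  expect_equal(detectJunctionPeak(p2), 0.75)
  # constant profile: no peak
  expect_error(detectJunctionPeak(IntensityProfile(0:4, rep(3, 5))),
               "constant")
  # noisy synthetic Gaussian: recovered within one pixel with smoothing
  px <- 0.2
  x <- seq(0, 30, by = px)
  set.seed(13)
  for (i in 1:20) {
    true <- 12.3
    v <- 100 * exp(-(x - true)^2 / (2 * 0.6^2)) +
      rnorm(length(x), sd = 3)
    got <- detectJunctionPeak(IntensityProfile(x, v), smoothSigmaUm = 0.5)
    expect_lt(abs(got - true), px)
  }
})

test_that("luminal background subtraction follows its contract", {
  p <- IntensityProfile(1:4, c(10, 8, 7, 12))
  out <- subtractLuminalBackground(p, c(2, 3))
  expect_equal(intensities(out), c(3, 1, 0, 5))
  expect_equal(out@background, 7)
  # constant profile becomes all zero
  out2 <- subtractLuminalBackground(IntensityProfile(1:4, rep(4, 4)),
                                    c(1, 2))
  expect_true(all(intensities(out2) == 0))
  # window minimum 0: identity
  p3 <- IntensityProfile(1:4, c(0, 2, 3, 4))
  expect_equal(intensities(subtractLuminalBackground(p3, c(1, 2))),
               c(0, 2, 3, 4))
  expect_error(subtractLuminalBackground(p, c(20, 30)), "overlap")
  expect_error(subtractLuminalBackground(p, c(3, 2)), "increasing")
})

test_that("identical shifted profiles align to zero dispersion", {
  x <- seq(0, 20, by = 0.5)
  shape <- function(x0) 50 * exp(-(x - x0)^2 / 4) + 10
  a <- IntensityProfile(x, shape(8))
  b <- IntensityProfile(x, shape(9.5))  # same shape shifted 3 px
  set <- alignAndAverage(list(a, b), peaksUm = c(8, 9.5),
                         trimUm = c(-6, 8))
  full <- set@nCover == 2
  expect_true(any(full))
  expect_true(all(abs(set@sem[full]) < 1e-9))
  ref <- 50 * exp(-set@x[full]^2 / 4) + 10
  expect_equal(set@mean[full], ref, tolerance = 1e-9)
})

test_that("averaging constants and replicates behaves as expected", {
  x <- 0:10
  c2 <- IntensityProfile(x, rep(2, 11)); c4 <- IntensityProfile(x, rep(4, 11))
  set <- alignAndAverage(list(c2, c4), peaksUm = c(5, 5),
                         trimUm = c(-5, 5))
  expect_true(all(abs(set@mean - 3) < 1e-12))
  # n noiseless replicates of one truth: mean is the truth, sem 0
  p <- smallScene(noiseSD = 0, seed = 1L)
  b <- generateProfileBundle(p)
  profs <- replicate(10, b$profiles$GFP, simplify = FALSE)
  peaks <- rep(p@junctionPosUm, 10)
  setR <- alignAndAverage(profs, peaks, trimUm = c(-5, 15))
  expect_equal(nDiscs(setR), 10)
  full <- setR@nCover == 10
  expect_true(all(setR@sem[full] == 0))
  truth <- approx(positions(b$profiles$GFP) - p@junctionPosUm,
                  intensities(b$profiles$GFP), xout = setR@x[full])$y
  expect_equal(setR@mean[full], truth, tolerance = 1e-9)
})

test_that("alignment is idempotent", {
  set.seed(31)
  x <- seq(0, 20, by = 0.4)
  profs <- lapply(1:4, function(i)
    IntensityProfile(x, 80 * exp(-(x - 8 - i * 0.4)^2 / 2) +
                        rnorm(length(x), sd = 1) + 20))
  peaks <- vapply(profs, detectJunctionPeak, 0)
  set1 <- alignAndAverage(profs, peaks, trimUm = c(-6, 10))
  # re-align the aligned members: peaks are now at 0 by construction
  members <- lapply(seq_len(nDiscs(set1)), function(i) {
    ok <- !is.na(set1@profiles[i, ])
    IntensityProfile(set1@x[ok], set1@profiles[i, ok])
  })
  set2 <- alignAndAverage(members, rep(0, length(members)),
                          trimUm = c(-6, 10))
  expect_identical(set2@x, set1@x)
  expect_equal(set2@profiles, set1@profiles, tolerance = 1e-12)
})

test_that("background subtraction commutes with alignment", {
  set.seed(32)
  x <- seq(0, 20, by = 0.4)
  # the window [0, 3] holds the global minimum, so subtraction never clamps
  # (clamping is the one nonlinearity that would break commutation)
  profs <- lapply(1:3, function(i)
    IntensityProfile(x, 60 * exp(-(x - 9)^2 / 2) + 15 +
                        (x > 3.5) * abs(rnorm(length(x)))))
  peaks <- rep(9, 3)
  win <- c(0, 3)
  subFirst <- alignAndAverage(lapply(profs, subtractLuminalBackground,
                                     luminalWindowUm = win),
                              peaks, trimUm = c(-6, 8))
  alignFirst <- alignAndAverage(profs, peaks, trimUm = c(-6, 8))
  # subtract each aligned member using the same (pre-shift) luminal window
  bg <- vapply(profs, function(p)
    min(intensities(p)[positions(p) >= win[1] & positions(p) <= win[2]]),
    0)
  shifted <- t(vapply(seq_len(3), function(i)
    pmax(0, alignFirst@profiles[i, ] - bg[i]),
    numeric(length(alignFirst@x))))
  expect_equal(shifted, subFirst@profiles, tolerance = 1e-9)
})

test_that("sem scales as sd over sqrt(n) on noisy replicates", {
  set.seed(33)
  x <- seq(0, 10, by = 0.5)
  profs <- lapply(1:12, function(i)
    IntensityProfile(x, 30 + 5 * exp(-(x - 5)^2) + rnorm(length(x))))
  set <- alignAndAverage(profs, rep(5, 12), trimUm = c(-5, 5))
  full <- set@nCover == 12
  expect_equal(set@sem[full], set@sd[full] / sqrt(12), tolerance = 1e-12)
})

test_that("alignment input contract errors", {
  expect_error(alignAndAverage(list(), numeric(0)), "at least one")
  p <- IntensityProfile(0:5, c(1, 2, 5, 2, 1, 1))
  expect_error(alignAndAverage(list(p), 99), "outside")
  expect_error(alignAndAverage(list(p), c(1, 2)), "one peak")
})
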