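test_that("partitions define the junctional band correctly", {
  expect_equal(junctionalBand(compartmentPartition()), c(-1, 1))
  expect_equal(junctionalBand(compartmentPartition(5, 1)), c(4, 6))
  expect_error(compartmentPartition(0, 0), "positive")
  expect_error(compartmentPartition(0, -2), "positive")
})

test_that("compartment fractions integrate and normalize correctly", {
  # all signal strictly apical
  x <- seq(-12, 30, by = 0.5)
  vApical <- ifelse(x < -3, 10, 0)
  frA <- compartmentFractions(IntensityProfile(x, vApical),
                              compartmentPartition())
  expect_equal(frA$fraction[frA$compartment == "apical"], 1.0)
  # uniform profile splits by extent: apical 10, junction 2, basolateral 30
  xu <- seq(-11, 31, by = 0.5)
  fru <- compartmentFractions(IntensityProfile(xu, rep(1, length(xu))),
                              compartmentPartition())
  expect_equal(fru$fraction, c(10, 2, 30) / 42, tolerance = 1e-9)
  # fractions sum to one and resist positive rescaling
  set.seed(21)
  v <- runif(length(xu))
  f1 <- compartmentFractions(IntensityProfile(xu, v),
                             compartmentPartition())
  f2 <- compartmentFractions(IntensityProfile(xu, 7.3 * v),
                             compartmentPartition())
  expect_equal(sum(f1$fraction), 1, tolerance = 1e-9)
  expect_equal(f1$fraction, f2$fraction, tolerance = 1e-12)
  expect_error(compartmentFractions(IntensityProfile(xu,
    rep(0, length(xu))), compartmentPartition()), "zero total")
})

test_that("a basolateral-only synthetic target has zero apical fraction", {
  p <- smallScene(targetMix = c(0, 0, 1, 0), noiseSD = 0, seed = 1L)
  truth <- truthFractions(p)
  expect_lt(truth$fraction[truth$compartment == "apical"], 0.01)
  expect_gt(truth$fraction[truth$compartment == "basolateral"], 0.9)
})

test_that("Welch comparison matches the closed-form worked example", {
  x <- 0
  mk <- function(vals) {
    new("AlignedProfileSet", x = c(-2, 0, 2),
        profiles = cbind(vals, vals, vals), channel = "GFP",
        mean = rep(mean(vals), 3), sd = rep(sd(vals), 3),
        sem = rep(sd(vals) / sqrt(length(vals)), 3),
        nCover = rep(length(vals), 3L), trim = c(-2, 2))
  }
  cmp <- compareProfiles(mk(1:5), mk(2:6))
  row <- cmp$positions[cmp$positions$x == 0, ]
  expect_equal(row$t, -1.0, tolerance = 1e-12)
  expect_equal(row$df, 8, tolerance = 1e-12)
  expect_equal(row$p, 0.3466, tolerance = 1e-3)
  expect_equal(row$p, 2 * pt(-1, 8), tolerance = 1e-12)
  # identical sets: t = 0, p = 1
  cmpSame <- compareProfiles(mk(1:5), mk(1:5))
  expect_true(all(cmpSame$positions$t == 0))
  expect_true(all(cmpSame$positions$p == 1))
  # zero variance, unequal means: machine-floor p with flag
  cmp0 <- compareProfiles(mk(rep(1, 4)), mk(rep(2, 4)))
  expect_true(all(cmp0$positions$zeroVariance))
  expect_true(all(cmp0$positions$p <= .Machine$double.xmin))
})

test_that("Welch columns agree with t.test on random draws", {
  set.seed(22)
  for (i in 1:25) {
    a <- rnorm(sample(3:9, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:9, 1), mean = runif(1, -1, 1))
    w <- apicobasal:::.welchFromSummaries(mean(a), var(a), length(a),
                                          mean(b), var(b), length(b))
    tt <- t.test(a, b)
    expect_equal(w$t, unname(tt$statistic), tolerance = 1e-9)
    expect_equal(w$df, unname(tt$parameter), tolerance = 1e-9)
    expect_equal(w$p, tt$p.value, tolerance = 1e-9)
  }
})

test_that("comparison input contract", {
  oneDisc <- new("AlignedProfileSet", x = 0:2,
                 profiles = matrix(1, 1, 3), channel = "GFP",
                 mean = rep(1, 3), sd = rep(NA_real_, 3),
                 sem = rep(NA_real_, 3), nCover = rep(1L, 3),
                 trim = c(0, 2))
  expect_error(compareProfiles(oneDisc, oneDisc), "at least 2")
})

test_that("Tukey-fence exclusion uses interpolated quartiles", {
  out <- excludeOutliers(c(10, 11, 12, 13, 14, 100))
  expect_equal(out$excluded, 100)
  expect_equal(out$retained, c(10, 11, 12, 13, 14))
  expect_equal(out$fences, c(7.5, 17.5), tolerance = 1e-12)
  # all-equal data: nothing excluded
  same <- excludeOutliers(rep(5, 6))
  expect_length(same$excluded, 0)
  # fewer than 4: unchanged with warning
  expect_warning(small <- excludeOutliers(c(1, 2, 3)), "fewer than 4")
  expect_equal(small$retained, c(1, 2, 3))
})

test_that("a trap-induced fraction shift is detected on synthetic discs", {
  ctrl <- smallSceneConfig(scene = list(target_mix = c(0, 0, 1, 0),
                                        noise_sd = 2),
                           n_discs = 6, seed = 51)
  ctrl$control_scene <- ctrl$scene
  ctrl$scene <- modifyList(ctrl$scene,
    list(target_mix = c(0.35, 0, 0.65, 0), trap_compartment = "apical",
         bound_fraction_max = 1))
  report <- runPipeline(ctrl)
  fr <- report$comparison$fractions
  expect_true(fr$significant[fr$compartment == "apical"])
  # the experimental apical mean fraction exceeds the control one
  expect_gt(fr$meanB[fr$compartment == "apical"],
            fr$meanA[fr$compartment == "apical"])
})
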