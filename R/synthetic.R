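#' Parameters for a synthetic epithelium cross-section
#'
#' Builds a validated \linkS4class{SceneParams} object describing a synthetic
#' pseudostratified epithelium sampled along its apical-basal axis. Defaults
#' emulate a wing-disc-like cross-section: a 114 um axis sampled at the
#' confocal z-step of 0.17 um, a luminal low-signal region over the first
#' 10 um, the junctional marker peak at 20 um with sigma 0.6 um, and a
#' basolateral membrane extending 45 um below the junction. The target
#' distribution is a weighted mix of apical, junctional, basolateral and
#' uniform components (default: basolateral-only, emulating a basolateral
#' membrane protein such as an Na/K-ATPase subunit).
#'
#' @param axisLengthUm sampled axis length (um), default 114.
#' @param pixelUm sampling step (um), default 0.17.
#' @param junctionPosUm true junction position (um), default 20.
#' @param junctionPeakSigmaUm junctional peak sigma (um), default 0.6.
#' @param lumenExtentUm luminal region length at the apical end (um),
#'   default 10.
#' @param basalExtentUm basolateral membrane extent below the junction (um),
#'   default 45.
#' @param targetMix weights of the (apical, junctional, basolateral, uniform)
#'   target components; non-negative, positive sum.
#' @param trapCompartment trap localization: "apical", "basolateral", "both",
#'   "ecm" or "none" (default).
#' @param boundFraction function of position (um) returning the bound target
#'   fraction in [0, 1]; default identically 0.
#' @param enhancementFactor fluorescence fold increase of the bound
#'   fluorophore at saturation, default 1.475.
#' @param noiseSD additive Gaussian noise sd (intensity units), default 0.
#' @param shotNoise logical, add Poisson shot noise, default FALSE.
#' @param seed integer RNG seed (required for any noisy generation).
#' @return A \linkS4class{SceneParams}.
#' @examples
#' sp <- sceneParams(targetMix = c(0, 0, 1, 0), seed = 1L)
#' sp
#' @export
sceneParams <- function(axisLengthUm = 114, pixelUm = 0.17,
                        junctionPosUm = 20, junctionPeakSigmaUm = 0.6,
                        lumenExtentUm = 10, basalExtentUm = 45,
                        targetMix = c(apical = 0, junctional = 0,
                                      basolateral = 1, uniform = 0),
                        trapCompartment = "none",
                        boundFraction = function(x) rep(0, length(x)),
                        enhancementFactor = 1.475,
                        noiseSD = 0, shotNoise = FALSE, seed = 1L) {
  new("SceneParams",
      axisLengthUm = as.numeric(axisLengthUm), pixelUm = as.numeric(pixelUm),
      junctionPosUm = as.numeric(junctionPosUm),
      junctionPeakSigmaUm = as.numeric(junctionPeakSigmaUm),
      lumenExtentUm = as.numeric(lumenExtentUm),
      basalExtentUm = as.numeric(basalExtentUm),
      targetMix = as.numeric(targetMix),
      trapCompartment = trapCompartment, boundFraction = boundFraction,
      enhancementFactor = as.numeric(enhancementFactor),
      noiseSD = as.numeric(noiseSD), shotNoise = isTRUE(shotNoise),
      seed = as.integer(seed))
}

# Smooth plateau indicator on [a, b] with logistic edges of scale `w` um.
.plateau <- function(x, a, b, w = 0.5) {
  stats::plogis((x - a) / w) * stats::plogis((b - x) / w)
}

# Normalized spatial components of the scene on grid x. All peak at ~1.
.sceneComponents <- function(p, x) {
  j <- p@junctionPosUm
  lum <- p@lumenExtentUm
  basalEnd <- min(p@axisLengthUm, j + p@basalExtentUm)
  apical <- .plateau(x, lum, j - p@junctionPeakSigmaUm)
  junctional <- exp(-(x - j)^2 / (2 * p@junctionPeakSigmaUm^2))
  basolateral <- .plateau(x, j + p@junctionPeakSigmaUm, basalEnd)
  uniform <- .plateau(x, lum, basalEnd)
  ecm <- exp(-(x - basalEnd)^2 / (2 * 1.0^2))
  list(apical = apical, junctional = junctional, basolateral = basolateral,
       uniform = uniform, ecm = ecm, basalEnd = basalEnd)
}

# Noiseless channel intensities of a scene: base amplitude 100, offset 5
# (so luminal background subtraction has something to remove).
.sceneTruth <- function(p) {
  # floor(length / step) samples starting at 0, matching the sample count
  # of a rectangular-ROI profile of the same length
  x <- (seq_len(floor(p@axisLengthUm / p@pixelUm)) - 1) * p@pixelUm
  comp <- .sceneComponents(p, x)
  offset <- 5
  w <- p@targetMix / sum(p@targetMix)
  target <- offset + 100 * (w[1] * comp$apical + w[2] * comp$junctional +
                            w[3] * comp$basolateral + w[4] * comp$uniform)
  # Junctional marker: sharp septate-junction peak over a weaker lateral
  # membrane pool; unique global max at the junction when noiseless.
  dlg <- offset + 100 * comp$junctional + 25 * comp$basolateral
  trap <- switch(p@trapCompartment,
    apical      = offset + 100 * comp$apical,
    basolateral = offset + 100 * comp$basolateral,
    both        = offset + 100 * comp$uniform,
    ecm         = offset + 100 * comp$ecm,
    none        = rep(0, length(x)))
  b <- p@boundFraction(x)
  observed <- target * (1 + (p@enhancementFactor - 1) * b)
  new("GroundTruth", x = x, targetTrue = target, trapTrue = trap,
      observed = observed, dlgTrue = dlg, junctionPosUm = p@junctionPosUm,
      boundFraction = b)
}

# Apply the scene's noise model to a vector (RNG state must be set by caller).
.addNoise <- function(v, p) {
  if (p@shotNoise) v <- stats::rpois(length(v), pmax(v, 0))
  if (p@noiseSD > 0) v <- v + stats::rnorm(length(v), sd = p@noiseSD)
  v
}

#' Generate a ground-truth-known profile bundle
#'
#' Produces the noiseless ground truth of a synthetic scene together with
#' noisy observed intensity profiles for the three channels: the junctional
#' marker ("Dlg"), the enhanced target ("GFP") and the trap ("GrabFP").
#' The observed target is \code{true * (1 + (F - 1) * boundFraction)} plus
#' noise. Deterministic given the seed in \code{params}.
#'
#' @param params a valid \linkS4class{SceneParams}.
#' @return list with elements \code{groundTruth} (\linkS4class{GroundTruth})
#'   and \code{profiles} (named list of \linkS4class{IntensityProfile}s:
#'   Dlg, GFP, GrabFP).
#' @examples
#' b <- generateProfileBundle(sceneParams(noiseSD = 2, seed = 7L))
#' b$profiles$Dlg
#' @export
generateProfileBundle <- function(params) {
  stopifnot(is(params, "SceneParams"))
  validObject(params)
  gt <- .sceneTruth(params)
  obs <- .withSeed(params@seed, list(
    Dlg = .addNoise(gt@dlgTrue, params),
    GFP = .addNoise(gt@observed, params),
    GrabFP = .addNoise(gt@trapTrue, params)))
  profiles <- mapply(function(v, ch) IntensityProfile(gt@x, v, channel = ch),
                     obs, names(obs), SIMPLIFY = FALSE)
  list(groundTruth = gt, profiles = profiles)
}

#' Generate a synthetic 2-D multichannel cross-section
#'
#' Renders the scene as a 2-D section: rows run along the apical-basal axis
#' (apical at row 1), columns across the section width. Each column carries
#' the scene's true intensity plus independent per-pixel noise, so averaging
#' across the width recovers the bundle profile (exactly when noiseless,
#' within ~3 * noiseSD / sqrt(width_px) pointwise otherwise).
#'
#' @param params a valid \linkS4class{SceneParams}.
#' @param widthUm section width (um), default 16.
#' @return An \linkS4class{ImageStack} with channels Dlg, GFP, GrabFP and
#'   square in-plane pixels of side \code{params@pixelUm}.
#' @export
generateCrossSection <- function(params, widthUm = 16) {
  stopifnot(is(params, "SceneParams"))
  validObject(params)
  if (widthUm <= 0) stop("widthUm must be positive")
  gt <- .sceneTruth(params)
  wPx <- max(1L, round(widthUm / params@pixelUm))
  nX <- length(gt@x)
  truths <- list(Dlg = gt@dlgTrue, GFP = gt@observed, GrabFP = gt@trapTrue)
  channels <- .withSeed(params@seed, lapply(truths, function(v) {
    m <- matrix(rep(v, wPx), nrow = nX, ncol = wPx)
    matrix(.addNoise(as.vector(m), params), nrow = nX, ncol = wPx)
  }))
  ImageStack(channels,
             voxelSize = c(y = params@pixelUm, x = params@pixelUm))
}

#' Generate a synthetic binder titration
#'
#' Emulates an in vitro fluorescence titration of an anti-GFP binder on a
#' fixed concentration of purified eGFP under a tight-binding occupancy
#' model: expected fluorescence is
#' \code{baseline * (1 + (trueF - 1) * min(1, binder / gfp))}, so the signal
#' rises linearly with binder up to the 1:1 stoichiometric point and
#' plateaus above it. Replicate noise is multiplicative Gaussian with
#' coefficient of variation \code{noiseCV}.
#'
#' @param trueF true fluorescence fold increase at saturation,
#'   default 1.475.
#' @param gfpNM eGFP concentration (nM), default 54.
#' @param binderNM binder concentrations (nM), default the 5-216 nM
#'   two-fold dilution ladder \code{c(0, 5, 13.5, 27, 54, 108, 216)} with a
#'   binder-free baseline well.
#' @param replicates replicate wells per concentration, default 5.
#' @param noiseCV replicate coefficient of variation, default 0.05.
#' @param baseline baseline fluorescence of unbound eGFP (arbitrary units),
#'   default 1000.
#' @param seed integer RNG seed.
#' @return A \linkS4class{TitrationSeries}.
#' @examples
#' ts <- generateTitration(seed = 3L)
#' ts
#' @export
generateTitration <- function(trueF = 1.475, gfpNM = 54,
                              binderNM = c(0, 5, 13.5, 27, 54, 108, 216),
                              replicates = 5, noiseCV = 0.05,
                              baseline = 1000, seed = 1L) {
  if (trueF < 1) stop("trueF must be >= 1")
  if (gfpNM <= 0) stop("gfpNM must be positive")
  if (any(binderNM < 0)) stop("binder concentrations must be >= 0")
  if (any(diff(binderNM) <= 0))
    stop("binder concentrations must be strictly increasing")
  if (replicates < 1) stop("replicates must be >= 1")
  if (noiseCV < 0) stop("noiseCV must be >= 0")
  occupancy <- pmin(1, binderNM / gfpNM)
  expected <- baseline * (1 + (trueF - 1) * occupancy)
  fluor <- .withSeed(seed, {
    m <- matrix(rep(expected, replicates), nrow = length(binderNM))
    if (noiseCV > 0)
      m <- m * (1 + matrix(stats::rnorm(length(m), sd = noiseCV),
                           nrow = nrow(m)))
    m
  })
  colnames(fluor) <- paste0("rep", seq_len(replicates))
  TitrationSeries(binderNM, fluor)
}
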