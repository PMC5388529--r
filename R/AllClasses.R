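#' @import methods
NULL

#' IntensityProfile: 1-D fluorescence intensity along the apical-basal axis
#'
#' Stores sampled fluorescence against position (micrometres) for a single
#' channel. Positions increase from apical (small x) to basal (large x).
#' The \code{background} slot records any luminal background value already
#' subtracted from \code{intensities}.
#'
#' @slot positions numeric, strictly increasing sample positions in um.
#' @slot intensities numeric, one intensity per position.
#' @slot channel character(1), channel label (e.g. "Dlg", "GFP", "GrabFP").
#' @slot background numeric(1), background value subtracted so far.
#'
#' @export
setClass("IntensityProfile",
  representation(
    positions   = "numeric",
    intensities = "numeric",
    channel     = "character",
    background  = "numeric"
  ),
  prototype(channel = NA_character_, background = 0)
)

setValidity("IntensityProfile", function(object) {
  msg <- character()
  if (length(object@positions) != length(object@intensities))
    msg <- c(msg, "positions and intensities must have equal length")
  if (length(object@positions) > 1 && any(diff(object@positions) <= 0))
    msg <- c(msg, "positions must be strictly increasing")
  if (length(object@channel) != 1)
    msg <- c(msg, "channel must be a single label")
  if (length(object@background) != 1 || !is.finite(object@background))
    msg <- c(msg, "background must be a single finite value")
  if (length(msg)) msg else TRUE
})

#' Construct an IntensityProfile
#'
#' @param positions numeric vector of sample positions (um), strictly
#'   increasing.
#' @param intensities numeric vector of intensities, same length.
#' @param channel channel label.
#' @param background background already subtracted (default 0).
#' @return An \linkS4class{IntensityProfile}.
#' @examples
#' p <- IntensityProfile(seq(0, 10, by = 0.5), runif(21), channel = "GFP")
#' positions(p)[1:3]
#' @export
IntensityProfile <- function(positions, intensities, channel = NA_character_,
                             background = 0) {
  new("IntensityProfile",
      positions = as.numeric(positions),
      intensities = as.numeric(intensities),
      channel = as.character(channel),
      background = as.numeric(background))
}

#' ImageStack: multichannel intensity volume with voxel sizes
#'
#' Each channel is a 2-D matrix (y, x) or 3-D array (z, y, x); all channels
#' share dimensions. Voxel sizes are per-axis spacings in micrometres, named
#' to match the array axes (e.g. \code{c(z = 0.17, y = 0.06, x = 0.06)} for a
#' high z-resolution confocal stack).
#'
#' @slot channels named list of numeric arrays, one per channel.
#' @slot voxelSize named numeric, per-axis spacing in um.
#'
#' @export
setClass("ImageStack",
  representation(channels = "list", voxelSize = "numeric"))

setValidity("ImageStack", function(object) {
  msg <- character()
  if (length(object@channels) == 0)
    msg <- c(msg, "at least one channel required")
  if (is.null(names(object@channels)) || any(!nzchar(names(object@channels))))
    msg <- c(msg, "channels must be named")
  dims <- lapply(object@channels, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) > 1)
    msg <- c(msg, "all channels must share dimensions")
  nd <- length(dims[[1]])
  if (!nd %in% c(2L, 3L))
    msg <- c(msg, "channels must be 2-D or 3-D arrays")
  if (length(object@voxelSize) != nd)
    msg <- c(msg, "voxelSize must have one spacing per array axis")
  if (any(!is.finite(object@voxelSize)) || any(object@voxelSize <= 0))
    msg <- c(msg, "voxel spacings must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct an ImageStack
#'
#' @param channels named list of numeric matrices/arrays sharing dimensions.
#' @param voxelSize named numeric vector of per-axis spacings in um; one entry
#'   per array dimension, ordered as the array axes.
#' @return An \linkS4class{ImageStack}.
#' @export
ImageStack <- function(channels, voxelSize) {
  new("ImageStack", channels = channels, voxelSize = voxelSize)
}

#' AlignedProfileSet: per-disc profiles on a junction-centred grid
#'
#' Profiles from individual discs registered so the junctional marker peak
#' sits at x = 0 (negative x = apical/luminal side), resampled to a common
#' grid, with pointwise mean, standard deviation and standard error. Grid
#' positions covered by fewer than two discs carry NA dispersion and are
#' flagged through \code{nCover}.
#'
#' @slot x numeric, common grid (um, 0 at the aligned junction peak).
#' @slot profiles numeric matrix, one row per disc, NA where a disc does not
#'   cover the grid position.
#' @slot channel character(1).
#' @slot mean numeric, pointwise mean over covering discs.
#' @slot sd numeric, pointwise standard deviation.
#' @slot sem numeric, pointwise standard error of the mean.
#' @slot nCover integer, discs covering each position.
#' @slot trim numeric(2), retained x-range (um relative to the junction).
#'
#' @export
setClass("AlignedProfileSet",
  representation(
    x = "numeric", profiles = "matrix", channel = "character",
    mean = "numeric", sd = "numeric", sem = "numeric",
    nCover = "integer", trim = "numeric"
  ))

setValidity("AlignedProfileSet", function(object) {
  msg <- character()
  if (ncol(object@profiles) != length(object@x))
    msg <- c(msg, "profiles must have one column per grid position")
  if (nrow(object@profiles) < 1)
    msg <- c(msg, "at least one disc required")
  for (s in c("mean", "sd", "sem"))
    if (length(slot(object, s)) != length(object@x))
      msg <- c(msg, sprintf("%s must match grid length", s))
  if (length(object@nCover) != length(object@x))
    msg <- c(msg, "nCover must match grid length")
  if (length(object@trim) != 2 || object@trim[1] >= object@trim[2])
    msg <- c(msg, "trim must be an increasing range")
  if (length(msg)) msg else TRUE
})

#' CorrectionModel: nanobody-induced fluorescence enhancement correction
#'
#' Holds the saturation enhancement fold F (default 1.475: bound fluorophore
#' fluoresces 1.475-fold brighter than free) and the normalized trap-occupancy
#' profile relGrabFP(x) in [0, 1] used to localize the correction.
#'
#' @slot factor numeric(1), enhancement fold at saturation, >= 1.
#' @slot relGrabFP \linkS4class{IntensityProfile} with intensities in [0, 1].
#' @slot mode character(1), "linear" (default) or "divisive".
#'
#' @export
setClass("CorrectionModel",
  representation(factor = "numeric", relGrabFP = "IntensityProfile",
                 mode = "character"))

setValidity("CorrectionModel", function(object) {
  msg <- character()
  if (length(object@factor) != 1 || !is.finite(object@factor) ||
      object@factor < 1)
    msg <- c(msg, "enhancement factor must be a single value >= 1")
  v <- object@relGrabFP@intensities
  if (length(v) && (min(v) < 0 || max(v) > 1))
    msg <- c(msg, "relGrabFP must lie in [0, 1]")
  if (!object@mode %in% c("linear", "divisive"))
    msg <- c(msg, "mode must be 'linear' or 'divisive'")
  if (length(msg)) msg else TRUE
})

#' TitrationSeries: binder titration fluorescence measurements
#'
#' Ordered binder concentrations (nM) with replicate fluorescence readings
#' per concentration, plus the baseline fluorescence (binder-free wells when
#' available, otherwise derived from the lowest-binder wells).
#'
#' @slot binderNM numeric, strictly increasing binder concentrations (nM).
#' @slot fluorescence numeric matrix, rows = concentrations, cols = replicates.
#' @slot baseline numeric(1), baseline fluorescence (NA if not yet set).
#'
#' @export
setClass("TitrationSeries",
  representation(binderNM = "numeric", fluorescence = "matrix",
                 baseline = "numeric"))

setValidity("TitrationSeries", function(object) {
  msg <- character()
  if (length(object@binderNM) < 1)
    msg <- c(msg, "at least one concentration required")
  if (any(diff(object@binderNM) <= 0))
    msg <- c(msg, "concentrations must be strictly increasing")
  if (nrow(object@fluorescence) != length(object@binderNM))
    msg <- c(msg, "one fluorescence row per concentration required")
  if (ncol(object@fluorescence) < 1)
    msg <- c(msg, "at least one replicate required")
  if (length(object@baseline) != 1)
    msg <- c(msg, "baseline must be a single value")
  if (length(msg)) msg else TRUE
})

#' Construct a TitrationSeries
#'
#' @param binderNM strictly increasing binder concentrations in nM.
#' @param fluorescence matrix of fluorescence values, rows matching
#'   \code{binderNM}, one column per replicate.
#' @param baseline baseline fluorescence; if NA and a 0 nM row exists its mean
#'   is used, otherwise the mean of the lowest-concentration row.
#' @return A \linkS4class{TitrationSeries}.
#' @export
TitrationSeries <- function(binderNM, fluorescence, baseline = NA_real_) {
  fluorescence <- as.matrix(fluorescence)
  if (is.na(baseline)) {
    i0 <- which(binderNM == 0)
    baseline <- if (length(i0)) mean(fluorescence[i0[1], ])
                else mean(fluorescence[1, ])
  }
  new("TitrationSeries", binderNM = as.numeric(binderNM),
      fluorescence = fluorescence, baseline = as.numeric(baseline))
}

#' CompartmentPartition: apical / junctional / basolateral bands
#'
#' The junctional band is the marker-peak position plus and minus a
#' half-width (default 1.0 um); apical is everything on the low-x side of
#' the band, basolateral everything on the high-x side.
#'
#' @slot center numeric(1), junction centre (um; 0 after alignment).
#' @slot halfWidth numeric(1), half-width of the junctional band (um), > 0.
#'
#' @export
setClass("CompartmentPartition",
  representation(center = "numeric", halfWidth = "numeric"))

setValidity("CompartmentPartition", function(object) {
  msg <- character()
  if (length(object@center) != 1 || !is.finite(object@center))
    msg <- c(msg, "center must be a single finite value")
  if (length(object@halfWidth) != 1 || !is.finite(object@halfWidth) ||
      object@halfWidth <= 0)
    msg <- c(msg, "halfWidth must be a single positive value")
  if (length(msg)) msg else TRUE
})

#' SceneParams: parameters of a synthetic epithelium cross-section
#'
#' Describes the ground-truth geometry and signal model used by the synthetic
#' generators: a pseudostratified epithelium sampled along its apical-basal
#' axis, with a luminal low-signal region at small x, a sharp junctional
#' marker peak, a target-protein distribution mixed from apical / junctional /
#' basolateral / uniform components, an optional trap channel confined to one
#' compartment, and occupancy-dependent fluorescence enhancement of the
#' target.
#'
#' @slot axisLengthUm numeric(1), sampled axis length (um).
#' @slot pixelUm numeric(1), sampling step (um).
#' @slot junctionPosUm numeric(1), true junction position (um).
#' @slot junctionPeakSigmaUm numeric(1), junctional marker peak sigma (um).
#' @slot lumenExtentUm numeric(1), apical-side luminal region length (um).
#' @slot basalExtentUm numeric(1), basolateral membrane extent below the
#'   junction (um).
#' @slot targetMix numeric(4), non-negative weights of the
#'   (apical, junctional, basolateral, uniform) target components.
#' @slot trapCompartment character(1), one of "apical", "basolateral",
#'   "both", "ecm", "none".
#' @slot boundFraction function(x) giving the bound fraction of the target
#'   in [0, 1] at position x (um).
#' @slot enhancementFactor numeric(1), fold fluorescence increase of the
#'   bound fluorophore, >= 1.
#' @slot noiseSD numeric(1), additive Gaussian noise sd.
#' @slot shotNoise logical(1), add Poisson-like shot noise.
#' @slot seed integer(1), RNG seed.
#'
#' @export
setClass("SceneParams",
  representation(
    axisLengthUm = "numeric", pixelUm = "numeric", junctionPosUm = "numeric",
    junctionPeakSigmaUm = "numeric", lumenExtentUm = "numeric",
    basalExtentUm = "numeric", targetMix = "numeric",
    trapCompartment = "character", boundFraction = "function",
    enhancementFactor = "numeric", noiseSD = "numeric", shotNoise = "logical",
    seed = "integer"
  ))

setValidity("SceneParams", function(object) {
  msg <- character()
  pos1 <- function(v) length(v) == 1 && is.finite(v) && v > 0
  if (!pos1(object@axisLengthUm)) msg <- c(msg, "axisLengthUm must be > 0")
  if (!pos1(object@pixelUm)) msg <- c(msg, "pixelUm must be > 0")
  if (!pos1(object@junctionPeakSigmaUm))
    msg <- c(msg, "junctionPeakSigmaUm must be > 0")
  if (!pos1(object@lumenExtentUm)) msg <- c(msg, "lumenExtentUm must be > 0")
  if (!pos1(object@basalExtentUm)) msg <- c(msg, "basalExtentUm must be > 0")
  if (length(object@junctionPosUm) != 1 ||
      object@junctionPosUm <= object@lumenExtentUm ||
      object@junctionPosUm >= object@axisLengthUm)
    msg <- c(msg, "junctionPosUm must lie between lumenExtentUm and axisLengthUm")
  if (length(object@targetMix) != 4 || any(object@targetMix < 0) ||
      sum(object@targetMix) <= 0)
    msg <- c(msg, "targetMix needs 4 non-negative weights with positive sum")
  if (!object@trapCompartment %in%
        c("apical", "basolateral", "both", "ecm", "none"))
    msg <- c(msg, "unknown trapCompartment")
  b <- object@boundFraction(seq(0, object@axisLengthUm, length.out = 64))
  if (any(!is.finite(b)) || any(b < 0) || any(b > 1))
    msg <- c(msg, "boundFraction must map positions into [0, 1]")
  if (length(object@enhancementFactor) != 1 || object@enhancementFactor < 1)
    msg <- c(msg, "enhancementFactor must be >= 1")
  if (length(object@noiseSD) != 1 || object@noiseSD < 0)
    msg <- c(msg, "noiseSD must be >= 0")
  if (length(msg)) msg else TRUE
})

#' GroundTruth: noiseless truth behind a synthetic scene
#'
#' The noiseless, unenhanced target profile, the trap profile, the true
#' junction position, and the noiseless observed target
#' \code{observed = true * (1 + (F - 1) * boundFraction)}, which is
#' pointwise >= the true profile with equality wherever the bound
#' fraction is zero.
#'
#' @slot x numeric, sample positions (um).
#' @slot targetTrue numeric, noiseless unenhanced target intensities.
#' @slot trapTrue numeric, noiseless trap intensities.
#' @slot observed numeric, enhanced (pre-noise) target intensities.
#' @slot dlgTrue numeric, noiseless junctional marker intensities.
#' @slot junctionPosUm numeric(1), true junction position (um).
#' @slot boundFraction numeric, bound fraction evaluated on \code{x}.
#'
#' @export
setClass("GroundTruth",
  representation(x = "numeric", targetTrue = "numeric", trapTrue = "numeric",
                 observed = "numeric", dlgTrue = "numeric",
                 junctionPosUm = "numeric", boundFraction = "numeric"))

setValidity("GroundTruth", function(object) {
  n <- length(object@x)
  lens <- c(length(object@targetTrue), length(object@trapTrue),
            length(object@observed), length(object@dlgTrue),
            length(object@boundFraction))
  if (any(lens != n)) return("all profile slots must match x in length")
  if (any(object@observed < object@targetTrue - 1e-9))
    return("observed must be >= targetTrue pointwise")
  TRUE
})

#' PolygonROI: polygonal region of interest for area quantification
#'
#' An ordered, simple (non-self-intersecting) polygon in pixel coordinates
#' with a pixel size for conversion to um^2.
#'
#' @slot vertices numeric matrix with columns x, y (pixels).
#' @slot pixelSizeUm numeric(1), side length of a pixel (um).
#'
#' @export
setClass("PolygonROI",
  representation(vertices = "matrix", pixelSizeUm = "numeric"))

setValidity("PolygonROI", function(object) {
  msg <- character()
  if (ncol(object@vertices) != 2)
    msg <- c(msg, "vertices must have two columns (x, y)")
  if (nrow(object@vertices) < 3)
    msg <- c(msg, "a polygon needs at least 3 vertices")
  if (length(object@pixelSizeUm) != 1 || object@pixelSizeUm <= 0)
    msg <- c(msg, "pixelSizeUm must be a single positive value")
  if (!length(msg) && .selfIntersects(object@vertices))
    msg <- c(msg, "polygon must be simple (non-self-intersecting)")
  if (!length(msg) && .shoelace(object@vertices) == 0)
    msg <- c(msg, "polygon must have non-zero area")
  if (length(msg)) msg else TRUE
})

#' Construct a PolygonROI
#'
#' @param vertices two-column matrix (or data.frame) of x, y vertex
#'   coordinates in pixels, in drawing order.
#' @param pixelSizeUm pixel side length in um (default 1, i.e. vertex
#'   coordinates already in um).
#' @return A \linkS4class{PolygonROI}.
#' @export
PolygonROI <- function(vertices, pixelSizeUm = 1) {
  v <- as.matrix(vertices)
  storage.mode(v) <- "double"
  colnames(v) <- c("x", "y")
  new("PolygonROI", vertices = v, pixelSizeUm = as.numeric(pixelSizeUm))
}
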