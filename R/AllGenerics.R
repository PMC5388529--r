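#' Sample positions of a profile or profile set
#'
#' @param object an \linkS4class{IntensityProfile} or
#'   \linkS4class{AlignedProfileSet}.
#' @return numeric vector of positions in um.
#' @export
setGeneric("positions", function(object) standardGeneric("positions"))

#' Intensity values of a profile
#'
#' @param object an \linkS4class{IntensityProfile}.
#' @return numeric vector of intensities.
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))

#' Channel label(s)
#'
#' @param object an object carrying channel information.
#' @return character vector of channel labels.
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))

#' Per-axis voxel spacing in um
#'
#' @param object an \linkS4class{ImageStack}.
#' @return named numeric vector of spacings.
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))

#' Number of discs (members) in an aligned set
#'
#' @param object an \linkS4class{AlignedProfileSet}.
#' @return integer count.
#' @export
setGeneric("nDiscs", function(object) standardGeneric("nDiscs"))

#' Pointwise mean profile of an aligned set
#'
#' @param object an \linkS4class{AlignedProfileSet}.
#' @return An \linkS4class{IntensityProfile} of the pointwise mean.
#' @export
setGeneric("meanProfile", function(object) standardGeneric("meanProfile"))

#' Pointwise dispersion of an aligned set
#'
#' @param object an \linkS4class{AlignedProfileSet}.
#' @param type "sem" (standard error, default) or "sd".
#' @return numeric vector on the set's grid.
#' @export
setGeneric("dispersion", function(object, type = c("sem", "sd"))
  standardGeneric("dispersion"))

#' @rdname positions
#' @export
setMethod("positions", "IntensityProfile", function(object) object@positions)

#' @rdname positions
#' @export
setMethod("positions", "AlignedProfileSet", function(object) object@x)

#' @rdname intensities
#' @export
setMethod("intensities", "IntensityProfile",
          function(object) object@intensities)

#' @rdname channelNames
#' @export
setMethod("channelNames", "IntensityProfile", function(object) object@channel)

#' @rdname channelNames
#' @export
setMethod("channelNames", "AlignedProfileSet", function(object) object@channel)

#' @rdname channelNames
#' @export
setMethod("channelNames", "ImageStack",
          function(object) names(object@channels))

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "ImageStack", function(object) object@voxelSize)

#' @rdname nDiscs
#' @export
setMethod("nDiscs", "AlignedProfileSet",
          function(object) nrow(object@profiles))

#' @rdname meanProfile
#' @export
setMethod("meanProfile", "AlignedProfileSet", function(object)
  IntensityProfile(object@x, object@mean, channel = object@channel))

#' @rdname dispersion
#' @export
setMethod("dispersion", "AlignedProfileSet", function(object, type) {
  type <- match.arg(type, c("sem", "sd"))
  if (type == "sem") object@sem else object@sd
})

setMethod("show", "IntensityProfile", function(object) {
  n <- length(object@positions)
  cat(sprintf("IntensityProfile [%s]: %d samples", object@channel, n))
  if (n) {
    cat(sprintf(", x in [%.3g, %.3g] um, intensity in [%.4g, %.4g]",
                object@positions[1], object@positions[n],
                min(object@intensities), max(object@intensities)))
    if (object@background != 0)
      cat(sprintf(", background %.4g subtracted", object@background))
  }
  cat("\n")
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@channels[[1]])
  cat(sprintf("ImageStack: %d channel(s) [%s], %s voxels, spacing (%s) um\n",
              length(object@channels),
              paste(names(object@channels), collapse = ", "),
              paste(d, collapse = " x "),
              paste(signif(object@voxelSize, 4), collapse = ", ")))
})

setMethod("show", "AlignedProfileSet", function(object) {
  cat(sprintf(
    "AlignedProfileSet [%s]: %d disc(s), grid %d points in [%.3g, %.3g] um (junction at 0)\n",
    object@channel, nrow(object@profiles), length(object@x),
    object@x[1], object@x[length(object@x)]))
})

setMethod("show", "CorrectionModel", function(object) {
  cat(sprintf(
    "CorrectionModel: F = %.4g, mode = %s, relGrabFP on %d positions (max %.3g)\n",
    object@factor, object@mode, length(object@relGrabFP@positions),
    if (length(object@relGrabFP@intensities))
      max(object@relGrabFP@intensities) else NA))
})

setMethod("show", "TitrationSeries", function(object) {
  cat(sprintf(
    "TitrationSeries: %d concentrations (%.4g-%.4g nM), %d replicate(s), baseline %.4g\n",
    length(object@binderNM), min(object@binderNM), max(object@binderNM),
    ncol(object@fluorescence), object@baseline))
})

setMethod("show", "SceneParams", function(object) {
  cat(sprintf(
    "SceneParams: axis %.4g um @ %.3g um/px, junction %.4g um, trap %s, F = %.4g, noise sd %.3g%s, seed %d\n",
    object@axisLengthUm, object@pixelUm, object@junctionPosUm,
    object@trapCompartment, object@enhancementFactor, object@noiseSD,
    if (object@shotNoise) " + shot" else "", object@seed))
})
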