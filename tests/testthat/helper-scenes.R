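# Shared fixtures: small, fast synthetic scenes and ground-truth helpers.

# A short axis keeps per-test generation cheap while preserving the
# geometry: lumen 0-6 um, junction at 12 um, basolateral to ~32 um.
smallScene <- function(...) {
  args <- list(axisLengthUm = 40, pixelUm = 0.2, junctionPosUm = 12,
               lumenExtentUm = 6, basalExtentUm = 20)
  dots <- list(...)
  for (k in names(dots)) args[[k]] <- dots[[k]]
  do.call(sceneParams, args)
}

# Ground-truth compartment fractions of a scene: the true (unenhanced)
# target profile, luminal background removed, on a junction-centred axis,
# restricted to the same disc-proper trim window the pipeline analyses.
truthFractions <- function(params, halfWidthUm = 1.0, trimUm = c(-10, 60)) {
  gt <- apicobasal:::.sceneTruth(params)
  bg <- min(gt@targetTrue[gt@x <= params@lumenExtentUm / 2])
  x <- gt@x - gt@junctionPosUm
  keep <- x >= trimUm[1] & x <= trimUm[2]
  prof <- IntensityProfile(x[keep], pmax(0, gt@targetTrue - bg)[keep])
  compartmentFractions(prof, compartmentPartition(0, halfWidthUm))
}

# Pipeline config for a synthetic condition on the small scene.
smallSceneConfig <- function(scene = list(), n_discs = 2, seed = 1,
                             ...) {
  base <- list(axis_length_um = 40, pixel_um = 0.2, junction_pos_um = 12,
               lumen_extent_um = 6, basal_extent_um = 20, noise_sd = 0)
  for (k in names(scene)) base[[k]] <- scene[[k]]
  c(list(scene = base, n_discs = n_discs, seed = seed,
         roi = list(length_um = 40, width_um = 8),
         luminal_window_um = c(0, 3), trim_um = c(-8, 25)),
    list(...))
}
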