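#' Default pipeline configuration
#'
#' Returns the default configuration list for \code{\link{runPipeline}},
#' documenting every tunable constant: ROI of 114 x 16 um, junctional band
#' half-width 1.0 um, luminal background window over the first 5 um,
#' disc-proper trim -10 to +60 um around the junction, enhancement factor
#' 1.475 with linear correction, alpha 0.05.
#'
#' @return named list of configuration defaults.
#' @export
defaultPipelineConfig <- function() {
  list(
    scene = list(
      axis_length_um = 114, pixel_um = 0.17, junction_pos_um = 20,
      junction_peak_sigma_um = 0.6, lumen_extent_um = 10,
      basal_extent_um = 45, target_mix = c(0, 0, 1, 0),
      trap_compartment = "none", bound_fraction_max = 0,
      enhancement_factor = 1.475, noise_sd = 0, shot_noise = FALSE),
    control_scene = NULL,
    stacks = NULL,
    n_discs = 8,
    seed = 1,
    roi = list(length_um = 114, width_um = 16),
    luminal_window_um = c(0, 5),
    junction_smooth_sigma_um = 0.5,
    junction_half_width_um = 1.0,
    trim_um = c(-10, 60),
    correction = list(enabled = TRUE, factor = 1.475, mode = "linear"),
    alpha = 0.05,
    output_dir = NULL
  )
}

# Merge user config over defaults (one level deep for the stage sub-lists).
# A control_scene block is merged over the pristine default scene so the
# control never inherits experimental-scene settings.
.mergeConfig <- function(config) {
  def <- defaultPipelineConfig()
  pristineScene <- def$scene
  fill <- function(base, user) {
    for (kk in names(user)) base[[kk]] <- user[[kk]]
    base
  }
  for (k in names(config)) {
    if (k %in% c("scene", "roi", "correction") && is.list(config[[k]]))
      def[[k]] <- fill(def[[k]], config[[k]])
    else if (k == "control_scene" && is.list(config[[k]]))
      def$control_scene <- fill(pristineScene, config[[k]])
    else def[[k]] <- config[[k]]
  }
  def
}

# SceneParams from a config scene block. The bound fraction follows the
# scene's own (noiseless, normalized) trap component scaled to
# bound_fraction_max, so occupancy peaks where trap is densest.
.sceneFromConfig <- function(sc, seed) {
  base <- sceneParams(
    axisLengthUm = sc$axis_length_um, pixelUm = sc$pixel_um,
    junctionPosUm = sc$junction_pos_um,
    junctionPeakSigmaUm = sc$junction_peak_sigma_um,
    lumenExtentUm = sc$lumen_extent_um, basalExtentUm = sc$basal_extent_um,
    targetMix = unlist(sc$target_mix),
    trapCompartment = sc$trap_compartment,
    enhancementFactor = sc$enhancement_factor,
    noiseSD = sc$noise_sd, shotNoise = isTRUE(sc$shot_noise),
    seed = seed)
  bmax <- if (is.null(sc$bound_fraction_max)) 0 else sc$bound_fraction_max
  if (bmax > 0 && sc$trap_compartment != "none") {
    gt0 <- .sceneTruth(base)
    occ <- pmax(0, gt0@trapTrue - min(gt0@trapTrue))
    occ <- if (max(occ) > 0) occ / max(occ) else occ
    bf <- stats::approxfun(gt0@x, pmin(1, bmax * occ), rule = 2)
    base@boundFraction <- bf
    validObject(base)
  }
  base
}

# One condition: generate (or load) per-disc sections, extract profiles,
# detect peaks, subtract luminal background, align and average per channel.
.runCondition <- function(sceneCfg, cfg, seedBase, stacks = NULL) {
  channels <- c("Dlg", "GFP", "GrabFP")
  nDisc <- if (is.null(stacks)) cfg$n_discs else length(stacks)
  perDisc <- vector("list", nDisc)
  roi <- profileROI(c(0, 0), lengthUm = cfg$roi$length_um,
                    widthUm = cfg$roi$width_um)
  seeds <- seedBase + seq_len(nDisc)
  for (i in seq_len(nDisc)) {
    if (is.null(stacks)) {
      params <- .sceneFromConfig(sceneCfg, seeds[i])
      section <- generateCrossSection(params, widthUm = cfg$roi$width_um)
    } else {
      st <- stacks[[i]]
      section <- loadStack(st$path,
                           voxelSizeUm = st$voxel_size_um)
      if (length(dim(section@channels[[1]])) == 3)
        section <- reslice(section, axis = st$reslice_axis,
                           index = st$reslice_index)
    }
    have <- intersect(channels, channelNames(section))
    prof <- lapply(have, function(ch) extractProfile(section, roi, ch))
    names(prof) <- have
    if (!"Dlg" %in% have)
      stop("pipeline requires a 'Dlg' junctional marker channel")
    peak <- detectJunctionPeak(prof$Dlg,
                               smoothSigmaUm = cfg$junction_smooth_sigma_um)
    prof <- lapply(prof, subtractLuminalBackground,
                   luminalWindowUm = cfg$luminal_window_um)
    perDisc[[i]] <- list(profiles = prof, peak = peak)
  }
  have <- names(perDisc[[1]]$profiles)
  peaks <- vapply(perDisc, `[[`, 0, "peak")
  sets <- stats::setNames(lapply(have, function(ch)
    alignAndAverage(lapply(perDisc, function(d) d$profiles[[ch]]),
                    peaks, trimUm = cfg$trim_um)), have)
  list(sets = sets, peaks = peaks, seeds = seeds)
}

# Apply the trap-occupancy correction to every member profile and the mean
# of a target set, reusing the set-average trap profile for relGrabFP.
.correctSet <- function(targetSet, trapSet, factor, mode) {
  trapMean <- meanProfile(trapSet)
  if (max(intensities(trapMean), na.rm = TRUE) <= 0) return(NULL)
  occ <- relGrabFP(trapMean)
  model <- correctionModel(occ, factor = factor, mode = mode)
  corr <- targetSet
  for (i in seq_len(nrow(corr@profiles))) {
    ok <- !is.na(corr@profiles[i, ])
    prof <- IntensityProfile(corr@x[ok], corr@profiles[i, ok])
    occi <- IntensityProfile(occ@positions[ok], occ@intensities[ok])
    corr@profiles[i, ok] <- intensities(
      correctProfile(prof, correctionModel(occi, factor, mode)))
  }
  nC <- corr@nCover
  corr@mean <- ifelse(nC >= 1, colMeans(corr@profiles, na.rm = TRUE),
                      NA_real_)
  corr@sd <- apply(corr@profiles, 2, stats::sd, na.rm = TRUE)
  corr@sd[nC < 2] <- NA_real_
  corr@sem <- corr@sd / sqrt(nC)
  list(set = corr, relGrabFP = occ, model = model)
}

#' Run the apical-basal quantification pipeline
#'
#' Executes the full chain
#' reslice/generate -> extract -> align -> background-subtract -> average ->
#' (enhancement-correct) -> partition -> fractions -> statistics on either
#' synthetic scenes (ground truth known) or stacks listed in the config,
#' and returns a report carrying complete provenance (package version,
#' config hash, all RNG seeds). When a control scene/condition is present,
#' the control profiles are compared against the (corrected, when enabled)
#' experimental profiles with two-sided Welch tests per position and per
#' compartment fraction.
#'
#' @param config configuration list (see \code{\link{defaultPipelineConfig}})
#'   or path to a YAML file with the same structure. Required content: a
#'   \code{scene} block (or \code{stacks} list) and a \code{roi} block;
#'   everything else has defaults.
#' @return list of class \code{"abPipelineReport"}: \code{conditions} (each
#'   with aligned sets, mean/corrected profiles, fraction tables, per-disc
#'   fractions, peaks, seeds), \code{comparison} (NULL without a control),
#'   \code{partition}, \code{provenance}.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!"roi" %in% names(config))
    stop("config error: an 'roi' block (length_um, width_um) is required")
  if (is.null(config$scene) && is.null(config$stacks))
    stop("config error: either a 'scene' block or a 'stacks' list is required")
  cfg <- .mergeConfig(config)
  if (is.null(cfg$roi$length_um) || is.null(cfg$roi$width_um))
    stop("config error: roi needs length_um and width_um")
  partition <- compartmentPartition(0, cfg$junction_half_width_um)
  withStage <- function(stage, expr)
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))

  conditions <- list()
  conditions$experimental <- withStage("extract/align",
    .runCondition(cfg$scene, cfg, seedBase = cfg$seed, stacks = cfg$stacks))
  if (!is.null(cfg$control_scene))
    conditions$control <- withStage("extract/align",
      .runCondition(cfg$control_scene, cfg, seedBase = cfg$seed + 10000L))

  for (nm in names(conditions)) {
    cond <- conditions[[nm]]
    corrected <- NULL
    if (isTRUE(cfg$correction$enabled) &&
        all(c("GFP", "GrabFP") %in% names(cond$sets)))
      corrected <- withStage("correction",
        .correctSet(cond$sets$GFP, cond$sets$GrabFP,
                    cfg$correction$factor, cfg$correction$mode))
    cond$corrected <- corrected
    target <- if (!is.null(corrected)) corrected$set else cond$sets$GFP
    cond$fractions <- withStage("fractions", list(
      raw = compartmentFractions(meanProfile(cond$sets$GFP), partition),
      final = compartmentFractions(meanProfile(target), partition),
      perDisc = perDiscFractions(target, partition)))
    conditions[[nm]] <- cond
  }

  comparison <- NULL
  if (length(conditions) == 2) {
    expTarget <- if (!is.null(conditions$experimental$corrected))
      conditions$experimental$corrected$set else
      conditions$experimental$sets$GFP
    comparison <- withStage("statistics",
      compareProfiles(conditions$control$sets$GFP, expTarget,
                      alpha = cfg$alpha, partition = partition))
  }

  report <- list(
    conditions = conditions,
    comparison = comparison,
    partition = partition,
    provenance = list(
      package = "apicobasal",
      version = as.character(utils::packageVersion("apicobasal")),
      configHash = .objectHash(cfg),
      config = cfg,
      seeds = lapply(conditions, `[[`, "seeds"),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  class(report) <- "abPipelineReport"
  if (!is.null(cfg$output_dir))
    withStage("write", .writeReport(report, cfg$output_dir))
  report
}

# Write report tables: per-condition aligned profile CSV blocks, fraction
# summaries, comparison statistics, and a YAML run log with provenance.
.writeReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report$conditions)) {
    cond <- report$conditions[[nm]]
    for (ch in names(cond$sets)) {
      s <- cond$sets[[ch]]
      tab <- data.frame(x_um = s@x)
      tab <- cbind(tab, t(s@profiles))
      names(tab)[-1] <- paste0("disc", seq_len(nrow(s@profiles)))
      tab$mean <- s@mean; tab$sd <- s@sd; tab$sem <- s@sem
      tab$n <- s@nCover
      if (ch == "GFP" && !is.null(cond$corrected))
        tab$mean_corrected <- cond$corrected$set@mean
      utils::write.csv(tab, file.path(dir,
        sprintf("profiles_%s_%s.csv", nm, ch)), row.names = FALSE)
    }
    utils::write.csv(cond$fractions$final,
      file.path(dir, sprintf("fractions_%s.csv", nm)), row.names = FALSE)
  }
  if (!is.null(report$comparison)) {
    utils::write.csv(report$comparison$positions,
      file.path(dir, "stats_positions.csv"), row.names = FALSE)
    utils::write.csv(report$comparison$fractions,
      file.path(dir, "stats_fractions.csv"), row.names = FALSE)
  }
  prov <- report$provenance
  prov$seeds <- lapply(prov$seeds, as.integer)
  prov$config$scene$target_mix <- as.numeric(prov$config$scene$target_mix)
  yaml::write_yaml(prov[c("package", "version", "configHash", "seeds",
                          "timestamp")],
                   file.path(dir, "run_log.yaml"))
  invisible(dir)
}

#' @export
print.abPipelineReport <- function(x, ...) {
  cat("apicobasal pipeline report\n")
  for (nm in names(x$conditions)) {
    cond <- x$conditions[[nm]]
    fr <- cond$fractions$final
    cat(sprintf("  %s: n = %d discs; fractions %s\n", nm,
                nrow(cond$fractions$perDisc),
                paste(sprintf("%s %.3f", fr$compartment, fr$fraction),
                      collapse = ", ")))
  }
  if (!is.null(x$comparison)) {
    sig <- x$comparison$fractions[x$comparison$fractions$significant, ,
                                  drop = FALSE]
    cat(sprintf("  comparison: %d/%d compartment fractions significant at alpha = %g\n",
                nrow(sig), nrow(x$comparison$fractions), x$comparison$alpha))
  }
  invisible(x)
}
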