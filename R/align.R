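#' Locate the junctional marker peak of a profile
#'
#' Position of the global maximum of the (optionally Gaussian-smoothed)
#' junctional marker profile, used as the landmark for aligning profiles
#' from different discs. When the maximum is attained on a plateau of
#' several samples, the plateau centroid is returned, so sub-pixel peak
#' positions are possible.
#'
#' @param profile an \linkS4class{IntensityProfile} (junctional marker
#'   channel); must not be constant.
#' @param smoothSigmaUm Gaussian smoothing sigma in um (0 = no smoothing).
#' @param tol values within \code{tol * (max - min)} of the maximum count as
#'   part of the maximal plateau; default 1e-9 (exact ties only).
#' @return numeric(1), peak position in um.
#' @examples
#' p <- IntensityProfile(seq(0, 2, by = 0.5), c(0, 1, 5, 2, 1))
#' detectJunctionPeak(p)  # 1.0
#' @export
detectJunctionPeak <- function(profile, smoothSigmaUm = 0, tol = 1e-9) {
  stopifnot(is(profile, "IntensityProfile"))
  x <- profile@positions
  v <- profile@intensities
  if (length(v) < 2 || diff(range(v)) == 0)
    stop("cannot locate a peak in a constant profile")
  if (smoothSigmaUm > 0) {
    dx <- if (length(x) > 1) min(diff(x)) else 1
    v <- .gaussSmooth(v, smoothSigmaUm, dx)
    if (diff(range(v)) == 0)
      stop("profile is constant after smoothing")
  }
  atMax <- which(v >= max(v) - tol * diff(range(v)))
  mean(x[atMax])
}

#' Subtract luminal background from a profile
#'
#' Removes the background fluorescence observed in the disc lumen: the
#' minimum intensity over the given luminal window is subtracted from the
#' whole profile and negative residuals are clamped to zero. The subtracted
#' value is recorded in the profile's \code{background} slot.
#'
#' @param profile an \linkS4class{IntensityProfile}.
#' @param luminalWindowUm numeric(2), position range (um) of the luminal
#'   region; must overlap the profile.
#' @return The corrected \linkS4class{IntensityProfile}.
#' @export
subtractLuminalBackground <- function(profile, luminalWindowUm) {
  stopifnot(is(profile, "IntensityProfile"))
  if (length(luminalWindowUm) != 2 ||
      luminalWindowUm[1] >= luminalWindowUm[2])
    stop("luminalWindowUm must be an increasing range")
  inWin <- profile@positions >= luminalWindowUm[1] &
           profile@positions <= luminalWindowUm[2]
  if (!any(inWin)) stop("luminal window does not overlap the profile")
  bg <- min(profile@intensities[inWin])
  IntensityProfile(profile@positions,
                   pmax(0, profile@intensities - bg),
                   channel = profile@channel,
                   background = profile@background + bg)
}

#' Align per-disc profiles by their junction peaks and average
#'
#' Each profile is shifted so that its junctional peak maps to x = 0 and
#' resampled by linear interpolation onto a common grid (the grid of the
#' first profile after shifting, extended to span all members; sub-pixel
#' shifts are supported). Pointwise mean, standard deviation and standard
#' error are computed over the discs covering each grid position; positions
#' covered by fewer than two discs get NA dispersion. The result is trimmed
#' to the disc-proper range \code{trimUm} (default -10 um apical to +60 um
#' basal of the junction).
#'
#' @param profiles list of \linkS4class{IntensityProfile}s, one per disc
#'   (same channel).
#' @param peaksUm numeric, junction peak position of each disc's marker
#'   profile (um), one per profile.
#' @param trimUm numeric(2), retained range around the junction (um),
#'   default \code{c(-10, 60)}.
#' @return An \linkS4class{AlignedProfileSet}.
#' @export
alignAndAverage <- function(profiles, peaksUm, trimUm = c(-10, 60)) {
  if (length(profiles) == 0) stop("at least one profile required")
  if (length(peaksUm) != length(profiles))
    stop("one peak position per profile required")
  for (i in seq_along(profiles)) {
    rng <- range(positions(profiles[[i]]))
    if (peaksUm[i] < rng[1] || peaksUm[i] > rng[2])
      stop(sprintf("peak %d (%.3g um) lies outside its profile", i,
                   peaksUm[i]))
  }
  if (length(trimUm) != 2 || trimUm[1] >= trimUm[2])
    stop("trimUm must be an increasing range")
  shifted <- lapply(seq_along(profiles), function(i)
    positions(profiles[[i]]) - peaksUm[i])
  # common grid: spacing of the first profile, spanning the union of
  # shifted ranges, phased so that x = 0 is a grid point
  dx <- min(diff(positions(profiles[[1]])))
  lo <- min(vapply(shifted, min, 0))
  hi <- max(vapply(shifted, max, 0))
  grid <- seq(floor(lo / dx), ceiling(hi / dx)) * dx
  mat <- t(vapply(seq_along(profiles), function(i)
    stats::approx(shifted[[i]], intensities(profiles[[i]]),
                  xout = grid)$y,
    numeric(length(grid))))
  keep <- grid >= trimUm[1] & grid <= trimUm[2]
  grid <- grid[keep]
  mat <- mat[, keep, drop = FALSE]
  nCover <- colSums(!is.na(mat))
  mu <- ifelse(nCover >= 1, colMeans(mat, na.rm = TRUE), NA_real_)
  sdv <- apply(mat, 2, stats::sd, na.rm = TRUE)
  sdv[nCover < 2] <- NA_real_
  sem <- sdv / sqrt(nCover)
  ch <- channelNames(profiles[[1]])
  new("AlignedProfileSet", x = grid, profiles = mat, channel = ch,
      mean = as.numeric(mu), sd = as.numeric(sdv), sem = as.numeric(sem),
      nCover = as.integer(nCover), trim = as.numeric(trimUm))
}
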