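#' Polygon area in um^2
#'
#' Shoelace area of a simple polygon scaled by the squared pixel size;
#' orientation-independent (absolute value).
#'
#' @param roi a \linkS4class{PolygonROI}.
#' @return numeric(1), area in um^2.
#' @examples
#' polygonArea(PolygonROI(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))))  # 1
#' @export
polygonArea <- function(roi) {
  stopifnot(is(roi, "PolygonROI"))
  validObject(roi)
  abs(.shoelace(roi@vertices)) * roi@pixelSizeUm^2
}

#' Relative area between experimental and control groups
#'
#' Ratio of group mean areas (experimental over control) after Tukey-fence
#' outlier exclusion in each group, with per-group dispersion, the ratio's
#' propagated standard error, and a two-sided Welch t-test between the
#' groups.
#'
#' @param experimental,control numeric vectors of areas (>= 2 each).
#' @return list with \code{ratio}, \code{ratioSE} (first-order propagation),
#'   \code{meanExp}, \code{meanCtrl}, \code{sdExp}, \code{sdCtrl},
#'   \code{excluded} (list), \code{t}, \code{df}, \code{p}.
#' @export
relativeArea <- function(experimental, control) {
  if (length(experimental) < 2 || length(control) < 2)
    stop("both groups need at least 2 areas")
  e <- excludeOutliers(experimental)
  c_ <- excludeOutliers(control)
  xe <- e$retained; xc <- c_$retained
  me <- mean(xe); mc <- mean(xc)
  if (mc == 0) stop("control mean area is zero")
  se <- stats::sd(xe); sc <- stats::sd(xc)
  ratio <- me / mc
  ratioSE <- abs(ratio) * sqrt((se / sqrt(length(xe)) / me)^2 +
                               (sc / sqrt(length(xc)) / mc)^2)
  tt <- stats::t.test(xe, xc)
  list(ratio = ratio, ratioSE = ratioSE, meanExp = me, meanCtrl = mc,
       sdExp = se, sdCtrl = sc,
       excluded = list(experimental = e$excluded, control = c_$excluded),
       t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Spatial range of a graded profile
#'
#' Distance from the profile maximum to the first position where the
#' profile falls below \code{thresholdFraction} of the maximum and stays
#' below it for at least two consecutive samples. Invariant to positive
#' rescaling. If the profile never stays below threshold the full extent
#' from the maximum is returned with \code{censored = TRUE}.
#'
#' @param profile an \linkS4class{IntensityProfile} with positive maximum.
#' @param thresholdFraction fraction of the maximum in (0, 1),
#'   default 0.1.
#' @return list with \code{rangeUm}, \code{censored}, \code{peakPosUm},
#'   \code{thresholdPosUm} (NA when censored).
#' @export
gradientRange <- function(profile, thresholdFraction = 0.1) {
  stopifnot(is(profile, "IntensityProfile"))
  if (thresholdFraction <= 0 || thresholdFraction >= 1)
    stop("thresholdFraction must lie in (0, 1)")
  x <- profile@positions
  v <- profile@intensities
  if (max(v) <= 0) stop("profile maximum must be positive")
  iMax <- which.max(v)
  thr <- thresholdFraction * max(v)
  below <- v < thr
  n <- length(v)
  for (i in seq(iMax, n)) {
    if (below[i] && (i == n || below[min(i + 1, n)])) {
      # below and stays below for >= 2 samples (or hits the profile end)
      if (i < n && !below[i + 1]) next
      return(list(rangeUm = x[i] - x[iMax], censored = FALSE,
                  peakPosUm = x[iMax], thresholdPosUm = x[i]))
    }
  }
  list(rangeUm = x[n] - x[iMax], censored = TRUE, peakPosUm = x[iMax],
       thresholdPosUm = NA_real_)
}

#' Read polygon ROIs from CSV or JSON
#'
#' CSV layout: columns \code{polygon, x, y} (one row per vertex, grouped by
#' the \code{polygon} identifier). JSON layout: an array of objects with
#' \code{x} and \code{y} vertex arrays (optionally a \code{name}).
#'
#' @param path file path ending in .csv or .json.
#' @param pixelSizeUm pixel size passed to every polygon, default 1.
#' @return named list of \linkS4class{PolygonROI}s.
#' @export
readPolygons <- function(path, pixelSizeUm = 1) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    out <- lapply(raw, function(p)
      PolygonROI(cbind(unlist(p$x), unlist(p$y)), pixelSizeUm))
    names(out) <- vapply(seq_along(raw), function(i) {
      nm <- raw[[i]]$name
      if (is.null(nm)) paste0("polygon", i) else nm
    }, "")
    out
  } else {
    tab <- utils::read.csv(path)
    if (!all(c("polygon", "x", "y") %in% names(tab)))
      stop("polygon CSV needs columns polygon, x, y")
    lapply(split(tab, tab$polygon), function(d)
      PolygonROI(cbind(d$x, d$y), pixelSizeUm))
  }
}
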