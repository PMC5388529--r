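#' Mean fluorescence of a well image region
#'
#' Arithmetic mean intensity over a well image (or a sub-region of it),
#' the per-well summary used for titration curves.
#'
#' @param image numeric matrix/array of intensities.
#' @param mask optional logical array of the same shape selecting the well
#'   region.
#' @return numeric(1), mean intensity.
#' @export
meanWellFluorescence <- function(image, mask = NULL) {
  v <- if (is.null(mask)) as.vector(image) else as.vector(image)[as.vector(mask)]
  if (length(v) == 0) stop("empty well region")
  mean(v)
}

#' Detect the saturation plateau of a titration
#'
#' Finds the largest terminal run of concentrations whose per-concentration
#' mean fluorescences are mutually within \code{relTol} (all pairwise
#' relative differences, scaled by the larger mean, below the tolerance).
#' If already the last two concentrations differ by \code{relTol} or more,
#' the plateau is empty. Baseline (0 nM) wells are not part of the ladder
#' scanned for a plateau.
#'
#' @param series a \linkS4class{TitrationSeries} with >= 3 non-baseline
#'   concentrations.
#' @param relTol relative tolerance for "no further increase",
#'   default 0.02.
#' @return numeric vector of plateau concentrations (possibly empty).
#' @export
detectPlateau <- function(series, relTol = 0.02) {
  stopifnot(is(series, "TitrationSeries"))
  keep <- series@binderNM > 0
  conc <- series@binderNM[keep]
  if (length(conc) < 3)
    stop("plateau detection requires at least 3 non-baseline concentrations")
  means <- rowMeans(series@fluorescence[keep, , drop = FALSE])
  n <- length(conc)
  relDiff <- function(a, b) abs(a - b) / max(abs(a), abs(b))
  start <- n  # plateau = conc[start..n]; shrink start while mutually flat
  for (s in (n - 1):1) {
    block <- means[s:n]
    flat <- TRUE
    for (i in seq_along(block))
      for (j in seq_along(block))
        if (j > i && relDiff(block[i], block[j]) >= relTol) flat <- FALSE
    if (flat) start <- s else break
  }
  if (start == n) return(numeric(0))
  conc[start:n]
}

#' Fold change in fluorescence at saturation
#'
#' Mean of all replicate data points at plateau concentrations divided by
#' the baseline fluorescence, with the percent increase, the median of the
#' plateau points, their dispersion, and the individual points retained.
#'
#' @param series a \linkS4class{TitrationSeries} with positive baseline.
#' @param plateauNM plateau concentrations, e.g. from
#'   \code{\link{detectPlateau}}; must be non-empty.
#' @return list with \code{fold}, \code{percentIncrease}, \code{median}
#'   (of per-point folds), \code{sd} (of per-point folds), \code{points}
#'   (per-point folds), \code{n}.
#' @export
foldChangeAtSaturation <- function(series, plateauNM) {
  stopifnot(is(series, "TitrationSeries"))
  if (length(plateauNM) == 0) stop("plateau set is empty")
  if (!all(plateauNM %in% series@binderNM))
    stop("plateau concentrations must be part of the series")
  if (!is.finite(series@baseline) || series@baseline <= 0)
    stop("baseline fluorescence must be positive")
  pts <- as.vector(series@fluorescence[series@binderNM %in% plateauNM, ,
                                       drop = FALSE])
  folds <- pts / series@baseline
  fold <- mean(folds)
  list(fold = fold, percentIncrease = (fold - 1) * 100,
       median = stats::median(folds), sd = stats::sd(folds),
       points = folds, n = length(folds))
}

#' Per-concentration significance of the fluorescence increase
#'
#' Two-sided t-test of each concentration's replicate fluorescence against
#' the baseline replicates. The equal-variance (Student) test is the
#' default used for titration wells; the unequal-variance (Welch) variant
#' is also available.
#'
#' @param series a \linkS4class{TitrationSeries} whose first row is the
#'   baseline (0 nM) wells.
#' @param varEqual logical, equal-variance test (default TRUE).
#' @return data.frame with conc_nM, meanFold, t, df, p per non-baseline
#'   concentration.
#' @export
titrationSignificance <- function(series, varEqual = TRUE) {
  stopifnot(is(series, "TitrationSeries"))
  i0 <- which(series@binderNM == 0)
  if (length(i0) == 0)
    stop("significance testing requires baseline (0 nM) wells")
  base <- series@fluorescence[i0[1], ]
  rows <- which(series@binderNM > 0)
  do.call(rbind, lapply(rows, function(i) {
    tt <- stats::t.test(series@fluorescence[i, ], base,
                        var.equal = varEqual)
    data.frame(conc_nM = series@binderNM[i],
               meanFold = mean(series@fluorescence[i, ]) / mean(base),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  }))
}

#' Imaging linearity check
#'
#' Least-squares line through measured fluorescence versus known fluorophore
#' concentration, verifying that imaging conditions sit in the linear range:
#' proportionality is flagged when the intercept lies within its standard
#' error of zero and R-squared reaches the threshold.
#'
#' @param knownConcNM known concentrations (>= 3 distinct values).
#' @param measured measured fluorescence, same length.
#' @param r2Threshold minimum R-squared, default 0.98.
#' @return list with \code{slope}, \code{intercept}, \code{interceptSE},
#'   \code{r2}, \code{proportional}.
#' @export
linearityCheck <- function(knownConcNM, measured, r2Threshold = 0.98) {
  if (length(knownConcNM) < 3 || length(measured) != length(knownConcNM))
    stop("need >= 3 matched concentration/measurement pairs")
  if (stats::var(knownConcNM) == 0)
    stop("concentrations have zero variance")
  fit <- stats::lm(measured ~ knownConcNM)
  sm <- summary(fit)
  # constant measurements carry no information about concentration
  r2 <- if (stats::var(measured) == 0) 0 else sm$r.squared
  co <- stats::coef(sm)
  intercept <- co[1, 1]
  intSE <- co[1, 2]
  list(slope = co[2, 1], intercept = intercept, interceptSE = intSE,
       r2 = r2,
       proportional = abs(intercept) <= intSE && r2 >= r2Threshold)
}
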