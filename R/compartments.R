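#' Partition the apical-basal axis into compartments
#'
#' The junctional band is the junction centre plus and minus a half-width
#' (default 1.0 um, i.e. the marker peak plus/minus 1 um); apical is
#' everything on the low-x side of the band, basolateral everything on the
#' high-x side.
#'
#' @param centerUm junction centre in um (0 on an aligned grid).
#' @param halfWidthUm junctional band half-width (um), > 0, default 1.0.
#' @return A \linkS4class{CompartmentPartition}.
#' @examples
#' compartmentPartition()  # band [-1, 1] around the aligned peak
#' @export
compartmentPartition <- function(centerUm = 0, halfWidthUm = 1.0) {
  new("CompartmentPartition", center = as.numeric(centerUm),
      halfWidth = as.numeric(halfWidthUm))
}

#' Compartment boundaries of a partition
#'
#' @param partition a \linkS4class{CompartmentPartition}.
#' @return numeric(2): the junctional band \code{c(lower, upper)} in um.
#' @export
junctionalBand <- function(partition) {
  stopifnot(is(partition, "CompartmentPartition"))
  c(partition@center - partition@halfWidth,
    partition@center + partition@halfWidth)
}

#' Integrated intensity and localization fractions per compartment
#'
#' Trapezoidal integration of a background-subtracted, trimmed profile over
#' the apical, junctional and basolateral compartments; fractions are each
#' compartment's integral over the total. Fractions are non-negative, sum
#' to 1 and are invariant under positive rescaling of the profile.
#'
#' @param profile an \linkS4class{IntensityProfile}.
#' @param partition a \linkS4class{CompartmentPartition}.
#' @return data.frame with columns \code{compartment}, \code{integral},
#'   \code{fraction}.
#' @export
compartmentFractions <- function(profile, partition) {
  stopifnot(is(profile, "IntensityProfile"),
            is(partition, "CompartmentPartition"))
  x <- profile@positions
  v <- profile@intensities
  band <- junctionalBand(partition)
  ints <- c(
    apical      = .trapzInterval(x, v, x[1], band[1]),
    junctional  = .trapzInterval(x, v, band[1], band[2]),
    basolateral = .trapzInterval(x, v, band[2], x[length(x)]))
  total <- sum(ints)
  if (total <= 0) stop("profile has zero total integral; cannot form fractions")
  data.frame(compartment = names(ints), integral = as.numeric(ints),
             fraction = as.numeric(ints / total), row.names = NULL)
}

#' Per-disc compartment fractions of an aligned set
#'
#' Computes \code{\link{compartmentFractions}} for every member profile of
#' an aligned set over the grid positions it covers.
#'
#' @param set an \linkS4class{AlignedProfileSet}.
#' @param partition a \linkS4class{CompartmentPartition}; default the
#'   standard band at the aligned junction (0 +/- 1 um).
#' @return matrix, rows = discs, columns apical/junctional/basolateral.
#' @export
perDiscFractions <- function(set, partition = compartmentPartition()) {
  stopifnot(is(set, "AlignedProfileSet"))
  out <- t(vapply(seq_len(nrow(set@profiles)), function(i) {
    ok <- !is.na(set@profiles[i, ])
    fr <- compartmentFractions(
      IntensityProfile(set@x[ok], set@profiles[i, ok],
                       channel = set@channel), partition)
    stats::setNames(fr$fraction, fr$compartment)
  }, c(apical = 0, junctional = 0, basolateral = 0)))
  out
}

#' Compare two aligned profile sets
#'
#' Two-sided Welch (unequal-variance) t-tests between conditions, performed
#' per grid position on the member profiles and per compartment on the
#' per-disc localization fractions. Per-position p-values are reported both
#' raw (the headline significance flag at \code{alpha} follows the raw
#' values) and Benjamini-Hochberg adjusted. Positions where both groups
#' have zero variance but unequal means are flagged and their p reported at
#' the machine floor.
#'
#' @param setA,setB \linkS4class{AlignedProfileSet}s with >= 2 members each,
#'   on grids sharing spacing and phase.
#' @param alpha significance level, default 0.05.
#' @param partition compartment partition for the fraction tests; default
#'   junction 0 +/- 1 um.
#' @return list with data.frames \code{positions} (x, meanA, meanB, t, df,
#'   p, q, significant, zeroVariance) and \code{fractions} (compartment,
#'   meanA, meanB, t, df, p, significant), plus \code{alpha}.
#' @export
compareProfiles <- function(setA, setB, alpha = 0.05,
                            partition = compartmentPartition()) {
  stopifnot(is(setA, "AlignedProfileSet"), is(setB, "AlignedProfileSet"))
  if (nrow(setA@profiles) < 2 || nrow(setB@profiles) < 2)
    stop("both sets need at least 2 members for a Welch comparison")
  x <- intersect(round(setA@x, 9), round(setB@x, 9))
  if (length(x) == 0) stop("the two sets share no grid positions")
  ia <- match(x, round(setA@x, 9)); ib <- match(x, round(setB@x, 9))
  A <- setA@profiles[, ia, drop = FALSE]
  B <- setB@profiles[, ib, drop = FALSE]
  colStats <- function(m) {
    n <- colSums(!is.na(m))
    list(m = colMeans(m, na.rm = TRUE),
         v = apply(m, 2, stats::var, na.rm = TRUE), n = n)
  }
  sA <- colStats(A); sB <- colStats(B)
  ok <- sA$n >= 2 & sB$n >= 2
  w <- .welchFromSummaries(sA$m, sA$v, sA$n, sB$m, sB$v, sB$n)
  p <- ifelse(ok, w$p, NA_real_)
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  posTab <- data.frame(x = x, meanA = sA$m, meanB = sB$m,
                       t = ifelse(ok, w$t, NA_real_),
                       df = ifelse(ok, w$df, NA_real_),
                       p = p, q = q,
                       significant = !is.na(p) & p < alpha,
                       zeroVariance = ok & w$zeroVariance)
  frA <- perDiscFractions(setA, partition)
  frB <- perDiscFractions(setB, partition)
  frTab <- do.call(rbind, lapply(colnames(frA), function(cmp) {
    wf <- .welchFromSummaries(mean(frA[, cmp]), stats::var(frA[, cmp]),
                              nrow(frA),
                              mean(frB[, cmp]), stats::var(frB[, cmp]),
                              nrow(frB))
    data.frame(compartment = cmp, meanA = mean(frA[, cmp]),
               meanB = mean(frB[, cmp]), t = wf$t, df = wf$df, p = wf$p,
               significant = wf$p < alpha)
  }))
  list(positions = posTab, fractions = frTab, alpha = alpha)
}

#' Tukey-fence outlier exclusion
#'
#' Boxplot-style outlier exclusion: values outside
#' \code{[Q1 - 1.5 IQR, Q3 + 1.5 IQR]} (quartiles by linear interpolation,
#' \code{quantile} type 7) are excluded and listed. With fewer than 4 values
#' nothing is excluded and a warning is raised.
#'
#' @param values numeric vector.
#' @return list with \code{retained}, \code{excluded}, \code{fences}
#'   (numeric(2)).
#' @examples
#' excludeOutliers(c(10, 11, 12, 13, 14, 100))$excluded  # 100
#' @export
excludeOutliers <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 4) {
    warning("fewer than 4 values; no outlier exclusion performed")
    return(list(retained = values, excluded = numeric(0),
                fences = c(-Inf, Inf)))
  }
  qs <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- qs[2] - qs[1]
  fences <- c(qs[1] - 1.5 * iqr, qs[2] + 1.5 * iqr)
  out <- values < fences[1] | values > fences[2]
  list(retained = values[!out], excluded = values[out], fences = fences)
}
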