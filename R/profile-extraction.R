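#' ProfileROI: rectangular profiling region
#'
#' A rectangle whose long axis runs along the apical-basal direction of a
#' resliced section. The default 114 x 16 um matches routine practice for
#' wing-disc cross-sections: 114 um along the axis, intensities averaged
#' across a 16 um width.
#'
#' @slot originUm numeric(2), (row, col) position of the ROI corner in um.
#' @slot lengthUm numeric(1), extent along the long (A-B) axis, > 0.
#' @slot widthUm numeric(1), extent across, > 0.
#' @slot direction character(1), long-axis direction: "down" (along rows,
#'   default) or "right" (along columns).
#'
#' @export
setClass("ProfileROI",
  representation(originUm = "numeric", lengthUm = "numeric",
                 widthUm = "numeric", direction = "character"))

setValidity("ProfileROI", function(object) {
  msg <- character()
  if (length(object@originUm) != 2 || any(!is.finite(object@originUm)) ||
      any(object@originUm < 0))
    msg <- c(msg, "originUm must be two non-negative coordinates (row, col)")
  if (object@lengthUm <= 0) msg <- c(msg, "lengthUm must be positive")
  if (object@widthUm <= 0) msg <- c(msg, "widthUm must be positive")
  if (!object@direction %in% c("down", "right"))
    msg <- c(msg, "direction must be 'down' or 'right'")
  if (length(msg)) msg else TRUE
})

#' Construct a ProfileROI
#'
#' @param originUm (row, col) corner position in um, default c(0, 0).
#' @param lengthUm long-axis extent in um, default 114.
#' @param widthUm cross extent in um, default 16.
#' @param direction "down" (long axis along rows, default) or "right".
#' @return A \linkS4class{ProfileROI}.
#' @export
profileROI <- function(originUm = c(0, 0), lengthUm = 114, widthUm = 16,
                       direction = "down") {
  new("ProfileROI", originUm = as.numeric(originUm),
      lengthUm = as.numeric(lengthUm), widthUm = as.numeric(widthUm),
      direction = direction)
}

#' Orthogonal reslice of a 3-D stack
#'
#' Extracts the orthogonal 2-D section through a 3-D (z, y, x) stack at a
#' fixed index along one axis, carrying the remaining two voxel spacings
#' into the section (so a y-reslice of an anisotropic confocal stack yields
#' a section whose row spacing is the z-step).
#'
#' @param stack a 3-D \linkS4class{ImageStack}.
#' @param axis axis held fixed: "z", "y" or "x".
#' @param index 1-based slice index along \code{axis}.
#' @return A 2-D \linkS4class{ImageStack}; for \code{axis = "y"} the section
#'   axes are (z, x), for "x" they are (z, y), for "z" they are (y, x).
#' @export
reslice <- function(stack, axis = c("y", "z", "x"), index) {
  stopifnot(is(stack, "ImageStack"))
  axis <- match.arg(axis)
  d <- dim(stack@channels[[1]])
  if (length(d) != 3) stop("reslice requires a 3-D stack")
  ax <- match(axis, c("z", "y", "x"))
  if (index < 1 || index > d[ax])
    stop(sprintf("plane index %d out of bounds along %s (1..%d)",
                 index, axis, d[ax]))
  vox <- stack@voxelSize
  take <- switch(axis,
    z = function(ch) ch[index, , ],
    y = function(ch) ch[, index, ],
    x = function(ch) ch[, , index])
  keep <- setdiff(c("z", "y", "x"), axis)
  ImageStack(lapply(stack@channels, take),
             voxelSize = stats::setNames(as.numeric(vox[keep]),
                                         c("y", "x")))
}

# Resample a 2-D section to square pixels at the finest in-plane spacing
# by separable linear interpolation. Returns list(channels, pixelUm).
.resampleIsotropic <- function(channels, rowUm, colUm) {
  if (abs(rowUm - colUm) < 1e-12)
    return(list(channels = channels, pixelUm = rowUm))
  pixelUm <- min(rowUm, colUm)
  d <- dim(channels[[1]])
  oldR <- (seq_len(d[1]) - 1) * rowUm
  oldC <- (seq_len(d[2]) - 1) * colUm
  newR <- seq(0, oldR[length(oldR)], by = pixelUm)
  newC <- seq(0, oldC[length(oldC)], by = pixelUm)
  out <- lapply(channels, function(m) {
    tmp <- apply(m, 2, function(col)
      stats::approx(oldR, col, xout = newR)$y)
    t(apply(tmp, 1, function(row)
      stats::approx(oldC, row, xout = newC)$y))
  })
  list(channels = out, pixelUm = pixelUm)
}

#' Extract an intensity profile from a section ROI
#'
#' Reproduces line-profile extraction over a rectangular region: at each
#' position along the ROI's long axis the intensity is the unweighted mean
#' across the ROI width. Anisotropic sections are first resampled to square
#' pixels at the finest in-plane spacing (linear interpolation) so profiles
#' land on a uniform um grid. Fractional-pixel ROI edges are snapped to the
#' nearest pixel with a warning.
#'
#' @param section a 2-D \linkS4class{ImageStack}.
#' @param roi a \linkS4class{ProfileROI} inside the section bounds.
#' @param channel channel label to profile.
#' @return An \linkS4class{IntensityProfile} with positions in um from the
#'   ROI origin.
#' @export
extractProfile <- function(section, roi, channel) {
  stopifnot(is(section, "ImageStack"), is(roi, "ProfileROI"))
  validObject(roi)
  d <- dim(section@channels[[1]])
  if (length(d) != 2) stop("extractProfile requires a 2-D section")
  if (!channel %in% names(section@channels))
    stop("channel not present in section: ", channel)
  iso <- .resampleIsotropic(section@channels[channel],
                            section@voxelSize[1], section@voxelSize[2])
  m <- iso$channels[[1]]
  px <- iso$pixelUm
  if (roi@direction == "right") {
    m <- t(m)
    origin <- rev(roi@originUm)
  } else origin <- roi@originUm
  toIdx <- function(um) um / px + 1
  r0 <- toIdx(origin[1]); c0 <- toIdx(origin[2])
  nL <- floor(roi@lengthUm / px)
  nW <- max(1L, round(roi@widthUm / px))
  snap <- function(v, what) {
    s <- round(v)
    if (abs(v - s) > 1e-6)
      warning(sprintf("ROI %s edge snapped to nearest pixel (%.3f -> %d)",
                      what, v, s))
    as.integer(s)
  }
  r0 <- snap(r0, "origin row"); c0 <- snap(c0, "origin col")
  rows <- r0:(r0 + nL - 1L)
  cols <- c0:(c0 + nW - 1L)
  if (rows[1] < 1 || rows[length(rows)] > nrow(m) ||
      cols[1] < 1 || cols[length(cols)] > ncol(m))
    stop("ROI extends outside the section bounds")
  vals <- rowMeans(m[rows, cols, drop = FALSE])
  IntensityProfile((rows - r0) * px, vals, channel = channel)
}
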