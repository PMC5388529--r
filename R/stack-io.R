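#' Write an ImageStack as multi-page TIFF plus metadata sidecar
#'
#' Channels (and, for 3-D stacks, slices within each channel) are written as
#' 32-bit float TIFF pages. Because baseline TIFF float samples are stored in
#' [0, 1], intensities are range-normalized on write and the offset/scale
#' pair is recorded, together with channel labels, dimensions and voxel sizes,
#' in a YAML sidecar (\code{<path>.yaml}) that \code{\link{loadStack}} uses
#' to restore the stack.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "ImageStack"))
  d <- dim(stack@channels[[1]])
  lo <- min(vapply(stack@channels, min, 0))
  hi <- max(vapply(stack@channels, max, 0))
  scale <- max(1e-12, hi - lo)
  pages <- list()
  for (ch in stack@channels) {
    if (length(d) == 2) {
      pages <- c(pages, list((ch - lo) / scale))
    } else {
      pages <- c(pages,
                 lapply(seq_len(d[1]), function(k) (ch[k, , ] - lo) / scale))
    }
  }
  ok <- tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  if (!ok) stop("failed to write TIFF: ", path)
  meta <- list(
    channels = as.list(names(stack@channels)),
    dim = as.integer(d),
    voxel_size_um = as.list(stats::setNames(as.numeric(stack@voxelSize),
                                            names(stack@voxelSize))),
    intensity_offset = lo,
    intensity_scale = scale)
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' Load an ImageStack from multi-page TIFF
#'
#' Reads a TIFF written by \code{\link{writeStack}} (or any multi-page TIFF
#' with a matching YAML sidecar). \code{channelMap} renames or subsets
#' channels: a named character vector mapping desired labels to labels
#' present in the file.
#'
#' @param path TIFF path; \code{<path>.yaml} must exist alongside.
#' @param channelMap optional named character vector,
#'   \code{c(newLabel = "fileLabel", ...)}; requesting a label absent from
#'   the file is an error.
#' @param voxelSizeUm optional per-axis spacing override (named numeric).
#' @return An \linkS4class{ImageStack}.
#' @export
loadStack <- function(path, channelMap = NULL, voxelSizeUm = NULL) {
  if (!file.exists(path)) stop("stack file not found: ", path)
  metaPath <- paste0(path, ".yaml")
  if (!file.exists(metaPath)) stop("stack metadata not found: ", metaPath)
  meta <- yaml::read_yaml(metaPath)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  labels <- unlist(meta$channels)
  d <- as.integer(unlist(meta$dim))
  scale <- as.numeric(meta$intensity_scale)
  offset <- if (is.null(meta$intensity_offset)) 0
            else as.numeric(meta$intensity_offset)
  perChannel <- length(pages) / length(labels)
  channels <- stats::setNames(vector("list", length(labels)), labels)
  for (i in seq_along(labels)) {
    pg <- pages[((i - 1) * perChannel + 1):(i * perChannel)]
    if (length(d) == 2) {
      channels[[i]] <- pg[[1]] * scale + offset
    } else {
      arr <- array(0, dim = d)
      for (k in seq_len(d[1])) arr[k, , ] <- pg[[k]]
      channels[[i]] <- arr * scale + offset
    }
  }
  vox <- unlist(meta$voxel_size_um)
  if (!is.null(voxelSizeUm)) vox <- voxelSizeUm
  if (!is.null(channelMap)) {
    missing <- setdiff(unname(channelMap), labels)
    if (length(missing))
      stop("channel(s) not found in ", path, ": ",
           paste(missing, collapse = ", "))
    channels <- stats::setNames(channels[unname(channelMap)],
                                names(channelMap))
  }
  ImageStack(channels, voxelSize = vox)
}

#' Write intensity profiles to a CSV table
#'
#' Writes one \code{position_um} column plus one column per profile. All
#' profiles must share the same position grid; an empty profile list writes
#' a header-only file with a warning.
#'
#' @param profiles named list of \linkS4class{IntensityProfile}s (names
#'   become column headers; unnamed lists use channel labels).
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeProfileTable <- function(profiles, path) {
  if (length(profiles) == 0) {
    warning("no profiles supplied; writing header-only table")
    utils::write.csv(data.frame(position_um = numeric(0)), path,
                     row.names = FALSE)
    return(invisible(path))
  }
  nms <- names(profiles)
  if (is.null(nms) || any(!nzchar(nms)))
    nms <- vapply(profiles, channelNames, "")
  grid <- positions(profiles[[1]])
  for (p in profiles)
    if (length(positions(p)) != length(grid) ||
        any(abs(positions(p) - grid) > 1e-9))
      stop("all profiles must share the same position grid")
  tab <- data.frame(position_um = grid)
  for (i in seq_along(profiles)) tab[[nms[i]]] <- intensities(profiles[[i]])
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read a profile table written by \code{writeProfileTable}
#'
#' @param path CSV path with a \code{position_um} column.
#' @return named list of \linkS4class{IntensityProfile}s.
#' @export
readProfileTable <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  if (!"position_um" %in% names(tab))
    stop("profile table must contain a position_um column")
  cols <- setdiff(names(tab), "position_um")
  stats::setNames(lapply(cols, function(cn)
    IntensityProfile(tab$position_um, tab[[cn]], channel = cn)), cols)
}

#' Write a titration series to CSV
#'
#' Layout: \code{conc_nM, rep1..repN}.
#'
#' @param series a \linkS4class{TitrationSeries}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeTitrationTable <- function(series, path) {
  stopifnot(is(series, "TitrationSeries"))
  tab <- data.frame(conc_nM = series@binderNM)
  tab <- cbind(tab, as.data.frame(series@fluorescence))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read a titration series from CSV
#'
#' @param path CSV with columns \code{conc_nM, rep1..repN}.
#' @return A \linkS4class{TitrationSeries}.
#' @export
readTitrationTable <- function(path) {
  tab <- utils::read.csv(path)
  if (!"conc_nM" %in% names(tab))
    stop("titration table must contain a conc_nM column")
  TitrationSeries(tab$conc_nM,
                  as.matrix(tab[, setdiff(names(tab), "conc_nM"),
                                drop = FALSE]))
}
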