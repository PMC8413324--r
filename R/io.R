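## Import/export: multi-page TIFF stacks, point-pattern CSV + window YAML,
## scene directories.

#' Read a multi-page TIFF into an ImageStack
#'
#' @param path TIFF file with one page per section.
#' @param spacing voxel spacing (dx, dy, dz) in um.
#' @param origin physical origin in um.
#' @return an [ImageStack-class]; intensities as stored (0-1 for integer
#'   TIFFs read by the tiff package).
#' @export
readStackTIFF <- function(path, spacing, origin = c(0, 0, 0)) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- simplify2array(pages)
  if (length(dim(arr)) == 2) dim(arr) <- c(dim(arr), 1L)
  ImageStack(arr, spacing, origin)
}

#' Write an ImageStack (or mask / label volume) as a multi-page TIFF
#'
#' Intensity stacks are rescaled to [0, 1] and written as 16-bit grayscale;
#' masks are written as 8-bit 0/255; label volumes as 32-bit floats holding
#' the integer labels.
#'
#' @param x an [ImageStack-class], [MaskStack-class] or [LabelVolume-class].
#' @param path output file.
#' @return invisibly, the range used for intensity rescaling.
#' @export
writeStackTIFF <- function(x, path) {
  arr <- stackData(x)
  if (is(x, "MaskStack")) {
    pages <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k])
    tiff::writeTIFF(pages, path, bits.per.sample = 8)
    return(invisible(c(0, 1)))
  }
  if (is(x, "LabelVolume")) {
    ## labels stored as 16-bit counts (value = label / 65535)
    pages <- lapply(seq_len(dim(arr)[3]),
                    function(k) matrix(arr[, , k] / 65535, dim(arr)[1]))
    tiff::writeTIFF(pages, path, bits.per.sample = 16)
    return(invisible(range(arr)))
  }
  rng <- range(arr)
  sc <- if (diff(rng) > 0) (arr - rng[1]) / diff(rng) else arr * 0
  pages <- lapply(seq_len(dim(sc)[3]), function(k) sc[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(rng)
}

#' Read a point pattern from CSV (+ window YAML)
#'
#' @param csvPath CSV with columns x, y, z (um).
#' @param window window as (Lx, Ly, Lz), a 2 x 3 matrix, or the path of a
#'   YAML file with fields `lo` and `hi` (or `box`).
#' @return a [PointPattern3D-class].
#' @export
readPointPatternCSV <- function(csvPath, window) {
  df <- utils::read.csv(csvPath)
  if (is.character(window) && length(window) == 1 && file.exists(window)) {
    y <- yaml::read_yaml(window)
    window <- if (!is.null(y$box)) as.numeric(y$box) else
      rbind(lo = as.numeric(y$lo), hi = as.numeric(y$hi))
  }
  marks <- df[setdiff(names(df), c("x", "y", "z"))]
  PointPattern3D(as.matrix(df[, c("x", "y", "z")]), window,
                 marks = if (ncol(marks)) marks else NULL)
}

#' Write a point pattern to CSV (+ window YAML)
#'
#' @param pattern a [PointPattern3D-class].
#' @param csvPath output CSV path.
#' @param yamlPath optional output YAML path for the window.
#' @return invisibly, `csvPath`.
#' @export
writePointPatternCSV <- function(pattern, csvPath, yamlPath = NULL) {
  df <- as.data.frame(patternCoords(pattern))
  mk <- patternMarks(pattern)
  if (ncol(mk)) df <- cbind(df, mk)
  utils::write.csv(df, csvPath, row.names = FALSE)
  if (!is.null(yamlPath)) {
    w <- patternWindow(pattern)
    yaml::write_yaml(list(lo = as.numeric(w[1, ]), hi = as.numeric(w[2, ])),
                     yamlPath)
  }
  invisible(csvPath)
}

#' Export a synthetic scene to a directory
#'
#' Writes stack.tif (16-bit grayscale), labels.tif (32-bit), cells.csv,
#' pattern.csv and params.yaml.
#'
#' @param scene a [SyntheticScene-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
writeScene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeStackTIFF(scene@stack, file.path(dir, "stack.tif"))
  writeStackTIFF(scene@truthLabels, file.path(dir, "labels.tif"))
  cells <- scene@cells
  cells$polygon <- NULL
  utils::write.csv(cells, file.path(dir, "cells.csv"), row.names = FALSE)
  writePointPatternCSV(scene@pattern, file.path(dir, "pattern.csv"),
                       file.path(dir, "window.yaml"))
  pr <- scene@params
  pr$seed <- pr$seed %||% NA
  yaml::write_yaml(pr, file.path(dir, "params.yaml"))
  invisible(dir)
}

#' Read a label TIFF written by [writeStackTIFF()]
#'
#' @param path TIFF path.
#' @param spacing voxel spacing in um.
#' @return a [LabelVolume-class].
#' @export
readLabelTIFF <- function(path, spacing) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- simplify2array(pages)
  if (length(dim(arr)) == 2) dim(arr) <- c(dim(arr), 1L)
  LabelVolume(round(arr * 65535), spacing)
}

#' Read an 8-bit mask TIFF as a MaskStack
#'
#' Values of 255 (or 1.0 after the tiff package's normalisation) are
#' accepted and normalised to 1.
#'
#' @param path TIFF path.
#' @param spacing voxel spacing in um.
#' @return a [MaskStack-class].
#' @export
readMaskTIFF <- function(path, spacing) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- simplify2array(pages)
  if (length(dim(arr)) == 2) dim(arr) <- c(dim(arr), 1L)
  MaskStack((arr > 0.5) * 1, spacing)
}
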