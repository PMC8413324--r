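## End-to-end convenience: stack -> segmentation -> labelled cells ->
## classification -> density, plus centroid matching against ground truth.

#' Run the full measurement pipeline on an image stack
#'
#' Segment (classical reference segmenter), label and filter components,
#' measure 3D morphometrics, classify pyramidal versus non-pyramidal cells
#' with the volume/sphericity mixture, screen oversized outliers, and
#' report the pyramidal number density inside the analysis window.
#'
#' @param stack an [ImageStack-class].
#' @param window analysis box: (Lx, Ly, Lz) or a 2 x 3 bounds matrix in the
#'   stack's physical coordinates; only cells with centroids inside are
#'   classified and counted.
#' @param seed seed for the classifier initialisation.
#' @param minVoxels,dropEdgeSections passed to [labelAndFilter()].
#' @param computeProfiles also extract per-section profiles.
#' @param ... passed to [referenceSegment()].
#' @return list: mask, labels, cells (with `label` column), density (mm^-3),
#'   pyramidalCount, windowVolumeMm3.
#' @export
runPipeline <- function(stack, window, seed = NULL, minVoxels = 8,
                        dropEdgeSections = 3, computeProfiles = FALSE, ...) {
  if (is.null(dim(window))) window <- rbind(lo = c(0, 0, 0),
                                            hi = as.numeric(window))
  mask <- referenceSegment(stack, ...)
  labels <- labelAndFilter(mask, minVoxels = minVoxels,
                           dropEdgeSections = dropEdgeSections)
  meas <- measureCells(labels, computeProfiles = computeProfiles)
  cells <- meas$cells
  if (nrow(cells) == 0) stop("no cells reconstructed")
  inWin <- cells$cx >= window[1, 1] & cells$cx <= window[2, 1] &
    cells$cy >= window[1, 2] & cells$cy <= window[2, 2] &
    cells$cz >= window[1, 3] & cells$cz <= window[2, 3]
  cells$inWindow <- inWin
  cls <- gmmSplit(cells[inWin, , drop = FALSE], seed = seed)
  lab <- rep(NA_character_, nrow(cells))
  lab[inWin] <- cls$labels
  lab[inWin] <- outlierFilter(cells[inWin, , drop = FALSE], lab[inWin])
  cells$label <- lab
  volMm3 <- prod(window[2, ] - window[1, ]) * 1e-9
  count <- sum(lab == "pyramidal", na.rm = TRUE)
  list(mask = mask, labels = labels, cells = cells,
       profiles = meas$profiles,
       gmm = cls$gmm,
       pyramidalCount = count,
       windowVolumeMm3 = volMm3,
       density = numberDensity(count, volMm3))
}

#' Match measured cells to ground-truth cells by nearest centroid
#'
#' Greedy one-to-one matching: truth cells in order of increasing nearest
#' distance claim their nearest unclaimed measured cell, up to `maxDist`.
#'
#' @param truth data.frame with x, y, z columns (ground-truth centroids).
#' @param measured data.frame with cx, cy, cz columns.
#' @param maxDist maximum matching distance (um).
#' @return integer vector: for each truth row, the matched measured row or
#'   NA.
#' @export
matchCentroids <- function(truth, measured, maxDist = 5) {
  nT <- nrow(truth); nM <- nrow(measured)
  out <- rep(NA_integer_, nT)
  if (nT == 0 || nM == 0) return(out)
  D <- outer(truth$x, measured$cx, "-")^2 +
    outer(truth$y, measured$cy, "-")^2 +
    outer(truth$z, measured$cz, "-")^2
  D <- sqrt(D)
  repeat {
    m <- which.min(D)
    if (!length(m) || D[m] > maxDist) break
    ti <- ((m - 1) %% nT) + 1
    mi <- ((m - 1) %/% nT) + 1
    out[ti] <- mi
    D[ti, ] <- Inf
    D[, mi] <- Inf
    if (all(!is.finite(D))) break
  }
  out
}
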