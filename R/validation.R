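## Objectwise validation by centroid-in-profile matching, point-count area
## and shrinkage estimation, and cross-subject summary aggregation.

#' Match reconstructed 3D objects by centroid-in-profile membership
#'
#' A reference object is a true positive when its (rounded) centroid voxel
#' lies inside a predicted object's profile in the centroid's section, a
#' false negative otherwise; false positives are predicted objects whose
#' centroids fall in no reference profile.  Edge-flagged objects (see
#' [labelAndFilter()]) are excluded from the tallies on both sides.
#'
#' @param reference,predicted [LabelVolume-class] objects of equal shape,
#'   both already filtered (validation mode: objects spanning at least 4
#'   consecutive sections, edge-section centroids flagged).
#' @param membership "section" tests the centroid voxel in its own section
#'   (the profile rule); "column" relaxes to any section at the same
#'   in-plane position.
#' @return list with counts (a [ConfusionCounts-class], TN = 0 by
#'   construction), `matches` (reference id -> predicted id or NA) and the
#'   reverse map `predMatches`.
#' @export
matchObjects3D <- function(reference, predicted,
                           membership = c("section", "column")) {
  membership <- match.arg(membership)
  if (!identical(dim(reference), dim(predicted)))
    stop("shape mismatch between reference and predicted volumes")
  hit <- function(vol, ctr) {
    arr <- stackData(vol)
    d <- dim(arr)
    i <- pmin(pmax(round(ctr[1]), 1), d[1])
    j <- pmin(pmax(round(ctr[2]), 1), d[2])
    k <- pmin(pmax(round(ctr[3]), 1), d[3])
    if (membership == "section") arr[i, j, k] else {
      v <- arr[i, j, ]
      if (any(v > 0)) v[v > 0][1] else 0L
    }
  }
  centroidsOf <- function(vol) {
    arr <- stackData(vol)
    d <- dim(arr)
    fg <- which(arr > 0L)
    if (!length(fg)) return(NULL)
    lv <- arr[fg]
    i <- ((fg - 1L) %% d[1]) + 1L
    j <- (((fg - 1L) %/% d[1]) %% d[2]) + 1L
    k <- ((fg - 1L) %/% (d[1] * d[2])) + 1L
    cbind(id = sort(unique(lv)),
          i = tapply(i, lv, mean), j = tapply(j, lv, mean),
          k = tapply(k, lv, mean))
  }
  refC <- centroidsOf(reference)
  prdC <- centroidsOf(predicted)
  dropEdge <- function(C, vol) {
    if (is.null(C) || !length(vol@edgeLabels)) return(C)
    C[!(C[, "id"] %in% vol@edgeLabels), , drop = FALSE]
  }
  refC <- dropEdge(refC, reference)
  prdC <- dropEdge(prdC, predicted)
  nRef <- if (is.null(refC)) 0L else nrow(refC)
  nPrd <- if (is.null(prdC)) 0L else nrow(prdC)
  matches <- rep(NA_integer_, nRef)
  for (q in seq_len(nRef)) {
    h <- hit(predicted, refC[q, c("i", "j", "k")])
    if (h > 0) matches[q] <- h
  }
  predMatches <- rep(NA_integer_, nPrd)
  for (q in seq_len(nPrd)) {
    h <- hit(reference, prdC[q, c("i", "j", "k")])
    if (h > 0) predMatches[q] <- h
  }
  TP <- sum(!is.na(matches))
  FN <- sum(is.na(matches))
  FP <- sum(is.na(predMatches))
  list(counts = ConfusionCounts(TP = TP, FP = FP, TN = 0, FN = FN),
       matches = if (nRef) data.frame(referenceId = refC[, "id"],
                                      predictedId = matches) else
         data.frame(referenceId = integer(), predictedId = integer()),
       predMatches = if (nPrd) data.frame(predictedId = prdC[, "id"],
                                          referenceId = predMatches) else
         data.frame(predictedId = integer(), referenceId = integer()))
}

#' Area from systematic point counting
#'
#' A = (number of test points hitting tissue) x (area per point).
#'
#' @param hitPoints number of test points on tissue (non-negative).
#' @param areaPerPoint area associated with one test point (mm^2, > 0).
#' @return area in mm^2.
#' @export
pointCountArea <- function(hitPoints, areaPerPoint) {
  if (hitPoints < 0) stop("hit count must be non-negative")
  if (areaPerPoint <= 0) stop("area per point must be positive")
  hitPoints * areaPerPoint
}

#' Areal shrinkage fraction
#'
#' (area before - area after) / (area before); negative values indicate
#' swelling and are allowed.
#'
#' @param before,after areas (mm^2); `before` must be positive.
#' @return shrinkage fraction.
#' @export
arealShrinkage <- function(before, after) {
  if (before <= 0) stop("area before processing must be positive")
  (before - after) / before
}

#' Aggregate per-subject means into cross-subject summaries
#'
#' Cross-subject mean, population standard deviation (divisor n — the
#' convention required to reproduce the published summary rows; the sample
#' SD with divisor n-1 does not), and the coefficient of variation
#' CV = SD / mean.
#'
#' @param x numeric vector (one value per subject) or a data.frame whose
#'   columns are aggregated separately.
#' @return for a vector, named vector (mean, sd, cv); for a data.frame, a
#'   data.frame with rows mean, sd, cv.
#' @export
aggregateSubjectStats <- function(x) {
  agg1 <- function(v) {
    if (length(v) < 2) stop("need at least 2 subjects")
    m <- mean(v)
    s <- sqrt(mean((v - m)^2))
    c(mean = m, sd = s, cv = s / m)
  }
  if (is.data.frame(x)) as.data.frame(lapply(x, agg1), row.names =
                                        c("mean", "sd", "cv"))
  else agg1(x)
}

#' Format a cross-subject summary the way the published table prints it
#'
#' Applies the per-column display precision (volume and orientation means
#' to integers, orientation SD to 1 decimal, sphericity and diameters to 2
#' decimals) and computes the displayed CV from the rounded SD and the
#' unrounded mean, rounded half-up to 2 decimals — the convention that
#' reproduces the published CV row exactly.
#'
#' @param subjectTable data.frame of per-subject means, one column per
#'   measure, with columns among volume, orientation, sphericity, diaL,
#'   diaAll.
#' @return data.frame with character columns and rows mean, sd, cv.
#' @export
formatSubjectSummary <- function(subjectTable) {
  digitsMean <- c(volume = 0, orientation = 0, sphericity = 2,
                  diaL = 2, diaAll = 2)
  digitsSD <- c(volume = 0, orientation = 1, sphericity = 2,
                diaL = 2, diaAll = 2)
  out <- lapply(names(subjectTable), function(nm) {
    a <- aggregateSubjectStats(subjectTable[[nm]])
    dM <- if (nm %in% names(digitsMean)) digitsMean[[nm]] else 2
    dS <- if (nm %in% names(digitsSD)) digitsSD[[nm]] else 2
    sdDisp <- roundHalfUp(a[["sd"]], dS)
    c(mean = roundHalfUp(a[["mean"]], dM),
      sd = sdDisp,
      cv = roundHalfUp(sdDisp / a[["mean"]], 2))
  })
  res <- as.data.frame(out)
  names(res) <- names(subjectTable)
  rownames(res) <- c("mean", "sd", "cv")
  res
}
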