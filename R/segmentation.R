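## Reference segmentation of synthetic stacks, mask ingestion, and the
## pixelwise validation metrics (sensitivity, precision, F1).

#' Classical reference segmentation of a grayscale stack
#'
#' A deterministic stand-in segmenter for synthetic stacks with controlled
#' contrast: per-slice Gaussian smoothing, a global threshold for dark
#' objects (Otsu by default), per-slice morphological opening, and hole
#' filling.  Externally produced masks remain first-class inputs via
#' [MaskStack()]; this function does not attempt to segment low-contrast
#' real tissue.
#'
#' @param stack an [ImageStack-class].
#' @param smoothSigma Gaussian sigma in um for per-slice smoothing.
#' @param threshold global intensity threshold; NULL uses Otsu's method on
#'   the smoothed stack.
#' @param openRadius radius (px) of the per-slice opening brush; 0 disables.
#' @param fillHoles fill enclosed background holes per slice.
#' @param minSeparation required foreground / background mean separation in
#'   pooled within-class SD units; below it the stack is declared empty of
#'   cells.  Splitting pure Gaussian noise at any threshold separates the
#'   class means by at most ~2.7 within-class SDs, so the default 4 rejects
#'   noise-only stacks while real two-level stacks sit far above it.
#' @return a [MaskStack-class] (1 = cell).
#' @export
referenceSegment <- function(stack, smoothSigma = 0.7, threshold = NULL,
                             openRadius = 1, fillHoles = TRUE,
                             minSeparation = 4) {
  img <- stackData(stack)
  if (length(img) == 0) stop("empty stack")
  sp <- voxelSpacing(stack)
  sig <- smoothSigma / sp[1:2]
  sm <- if (smoothSigma > 0) .gaussianSmooth(img, c(sig, 0)) else img
  if (is.null(threshold)) {
    threshold <- .otsu(as.vector(sm))
    fg <- sm < threshold
    if (any(fg) && any(!fg)) {
      m1 <- mean(sm[fg]); m0 <- mean(sm[!fg])
      s <- sqrt(stats::weighted.mean(
        c(stats::var(sm[fg]), stats::var(sm[!fg])),
        c(sum(fg), sum(!fg)), na.rm = TRUE))
      if (!is.finite(s) || s <= 0) s <- 1e-12
      if ((m0 - m1) / s < minSeparation) {
        return(MaskStack(array(0, dim(img)), sp, origin = stackOrigin(stack)))
      }
    }
  }
  mask <- (sm < threshold) * 1
  if (any(mask > 0)) {
    ## EBImage morphology applies the 2D brush frame-by-frame on 3D arrays
    if (openRadius > 0)
      mask <- EBImage::opening(mask, EBImage::makeBrush(2 * openRadius + 1,
                                                        shape = "disc"))
    if (fillHoles) mask <- EBImage::fillHull(mask)
    mask <- (mask > 0.5) * 1
  }
  MaskStack(mask, sp, origin = stackOrigin(stack))
}

#' Pixelwise confusion counts between a reference and a predicted mask
#'
#' @param reference,predicted [MaskStack-class] objects of identical shape
#'   (or plain arrays with values in 0/1).
#' @return a [ConfusionCounts-class]: TP where both are 1, FP where only the
#'   prediction is 1, FN where only the reference is 1, TN elsewhere.
#' @export
pixelConfusion <- function(reference, predicted) {
  r <- if (is(reference, "MaskStack")) stackData(reference) else reference
  p <- if (is(predicted, "MaskStack")) stackData(predicted) else predicted
  if (!identical(dim(r), dim(p)))
    stop("shape mismatch between reference and predicted masks")
  r <- as.vector(r) > 0
  p <- as.vector(p) > 0
  ConfusionCounts(TP = sum(r & p), FP = sum(!r & p),
                  TN = sum(!r & !p), FN = sum(r & !p))
}

#' Sensitivity, precision and F1-score from confusion counts
#'
#' sensitivity = TP / (TP + FN); precision = TP / (TP + FP);
#' F1 = 2 * sensitivity * precision / (sensitivity + precision).
#'
#' @param counts a [ConfusionCounts-class], or anything coercible via
#'   [ConfusionCounts()] fields TP / FP / FN.
#' @return named numeric vector (sensitivity, precision, f1).
#' @export
classificationMetrics <- function(counts) {
  cv <- confusionVector(counts)
  if (cv["TP"] + cv["FN"] <= 0)
    stop("undefined metric: TP + FN is zero (no positives in reference)")
  if (cv["TP"] + cv["FP"] <= 0)
    stop("undefined metric: TP + FP is zero (no positives predicted)")
  sens <- cv[["TP"]] / (cv[["TP"]] + cv[["FN"]])
  prec <- cv[["TP"]] / (cv[["TP"]] + cv[["FP"]])
  f1 <- 2 * sens * prec / (sens + prec)
  c(sensitivity = sens, precision = prec, f1 = f1)
}

#' Round metrics for tabular reporting (2 decimals, half-up)
#'
#' @param metrics named numeric vector from [classificationMetrics()].
#' @param digits decimals to keep.
#' @return rounded named numeric vector.
#' @export
reportMetrics <- function(metrics, digits = 2) {
  roundHalfUp(metrics, digits)
}

#' Dice coefficient between two binary masks
#'
#' @param a,b masks ([MaskStack-class] or arrays).
#' @return 2 TP / (2 TP + FP + FN).
#' @export
diceCoefficient <- function(a, b) {
  cc <- confusionVector(pixelConfusion(a, b))
  2 * cc["TP"] / (2 * cc["TP"] + cc["FP"] + cc["FN"])
}
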