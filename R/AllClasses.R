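#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib CortexMorph, .registration = TRUE
NULL

## ---------------------------------------------------------------------------
## Voxel containers
## ---------------------------------------------------------------------------

.validVoxels <- function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3)
    msg <- c(msg, "'data' must be a 3D array")
  if (length(object@spacing) != 3 || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be 3 strictly positive values (um)")
  if (length(object@origin) != 3 || any(!is.finite(object@origin)))
    msg <- c(msg, "'origin' must be 3 finite values (um)")
  if (length(msg)) msg else TRUE
}

#' ImageStack: a 3D grayscale intensity grid with physical voxel spacing
#'
#' Dimension 1 is the in-plane x-axis (pointing toward the pial surface by
#' package convention), dimension 2 the in-plane y-axis, dimension 3 the
#' sectioning (z) axis.  All physical coordinates are in micrometres; the
#' centre of voxel (i, j, k) sits at origin + ((i, j, k) - 0.5) * spacing.
#'
#' @slot data 3D numeric array of intensities.
#' @slot spacing voxel spacing (dx, dy, dz) in um.
#' @slot origin physical coordinate of the corner of voxel (1, 1, 1), um.
#' @export
setClass("ImageStack",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  prototype(origin = c(0, 0, 0)),
  validity = .validVoxels)

#' MaskStack: a binary 3D mask (1 = cell pixel, 0 = background)
#'
#' @slot data 3D array with values in {0, 1}.
#' @slot spacing,origin as in [ImageStack-class].
#' @export
setClass("MaskStack",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  prototype(origin = c(0, 0, 0)),
  validity = function(object) {
    v <- .validVoxels(object)
    if (!isTRUE(v)) return(v)
    if (any(object@data != 0 & object@data != 1))
      return("mask values must all be 0 or 1")
    TRUE
  })

#' LabelVolume: a 3D labelled volume of reconstructed objects
#'
#' Labels are contiguous positive integers (0 = background).  Labels whose
#' centroid section lies within the configured number of edge sections are
#' recorded in `edgeLabels` (marked, not deleted).
#'
#' @slot data 3D integer array of labels.
#' @slot spacing,origin as in [ImageStack-class].
#' @slot edgeLabels integer vector of edge-flagged labels.
#' @export
setClass("LabelVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric",
                 edgeLabels = "integer"),
  prototype(origin = c(0, 0, 0), edgeLabels = integer()),
  validity = function(object) {
    v <- .validVoxels(object)
    if (!isTRUE(v)) return(v)
    if (any(object@data < 0)) return("labels must be non-negative")
    TRUE
  })

#' @rdname ImageStack-class
#' @param data,spacing,origin see slots.
#' @export
ImageStack <- function(data, spacing, origin = c(0, 0, 0)) {
  new("ImageStack", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' @rdname MaskStack-class
#' @param data,spacing,origin see slots.  Values of 255 (8-bit exports) are
#'   normalised to 1.
#' @export
MaskStack <- function(data, spacing, origin = c(0, 0, 0)) {
  if (max(data) == 255) data <- data / 255
  storage.mode(data) <- "double"
  new("MaskStack", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' @rdname LabelVolume-class
#' @param data,spacing,origin,edgeLabels see slots.
#' @export
LabelVolume <- function(data, spacing, origin = c(0, 0, 0),
                        edgeLabels = integer()) {
  storage.mode(data) <- "integer"
  new("LabelVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin), edgeLabels = as.integer(edgeLabels))
}

## ---------------------------------------------------------------------------
## Point patterns and cylindrical K summaries
## ---------------------------------------------------------------------------

#' PointPattern3D: centroid coordinates in a box observation window
#'
#' @slot coords n x 3 matrix of (x, y, z) in um.
#' @slot window 2 x 3 matrix, rows "lo" and "hi", the axis-aligned box (um).
#' @slot marks data.frame of per-point marks (may have zero columns).
#' @export
setClass("PointPattern3D",
  representation(coords = "matrix", window = "matrix", marks = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@coords) != 3) msg <- c(msg, "'coords' must have 3 columns")
    if (!all(dim(object@window) == c(2, 3)))
      msg <- c(msg, "'window' must be a 2 x 3 matrix (rows lo, hi)")
    else {
      if (any(object@window[2, ] <= object@window[1, ]))
        msg <- c(msg, "window must have positive extent on every axis")
      else if (nrow(object@coords) > 0) {
        eps <- 1e-9
        inW <- object@coords >= rep(object@window[1, ] - eps, each = nrow(object@coords)) &
               object@coords <= rep(object@window[2, ] + eps, each = nrow(object@coords))
        if (!all(inW)) msg <- c(msg, "all points must lie inside the window")
      }
    }
    if (nrow(object@marks) && nrow(object@marks) != nrow(object@coords))
      msg <- c(msg, "'marks' must have one row per point")
    if (length(msg)) msg else TRUE
  })

#' @rdname PointPattern3D-class
#' @param coords n x 3 matrix of coordinates (um).
#' @param window either (Lx, Ly, Lz) for a box with corner at the origin, or
#'   a 2 x 3 matrix of lower / upper bounds.
#' @param marks optional data.frame of per-point marks.
#' @export
PointPattern3D <- function(coords, window, marks = NULL) {
  coords <- as.matrix(coords)
  if (length(coords) == 0) coords <- matrix(numeric(), 0, 3)
  colnames(coords) <- c("x", "y", "z")
  if (is.null(dim(window))) {
    window <- rbind(lo = c(0, 0, 0), hi = as.numeric(window))
  } else {
    window <- as.matrix(window)
    rownames(window) <- c("lo", "hi")
  }
  if (is.null(marks)) marks <- data.frame()[seq_len(nrow(coords)), , drop = FALSE]
  new("PointPattern3D", coords = coords, window = window, marks = marks)
}

#' CylKEstimate: cylindrical K-function values on an (r, t) grid
#'
#' @slot direction unit vector u of the cylinder axis.
#' @slot r,t grid values (um).
#' @slot K matrix of K estimates, dim (length(r), length(t)).
#' @slot n number of points of the pattern.
#' @slot window observation window of the pattern.
#' @export
setClass("CylKEstimate",
  representation(direction = "numeric", r = "numeric", t = "numeric",
                 K = "matrix", n = "integer", window = "matrix"),
  validity = function(object) {
    msg <- character()
    if (any(object@K < -1e-9)) msg <- c(msg, "K must be non-negative")
    if (!all(dim(object@K) == c(length(object@r), length(object@t))))
      msg <- c(msg, "dim(K) must match the (r, t) grid")
    if (length(msg)) msg else TRUE
  })

#' GlobalEnvelope: an extreme-rank-length global envelope test result
#'
#' @slot estimate the observed [CylKEstimate-class].
#' @slot lower,upper envelope bound surfaces (same dim as the K grid).
#' @slot nsim number of null simulations.
#' @slot level envelope level (e.g. 0.95).
#' @slot pValue Monte-Carlo p-value of the ERL test.
#' @slot pInterval lower / upper p bounds from tie handling.
#' @slot erlRank rank of the observed curve under ERL ordering (1 = most
#'   extreme).
#' @slot decision character matrix: "above", "inside" or "below" per cell.
#' @export
setClass("GlobalEnvelope",
  representation(estimate = "CylKEstimate", lower = "matrix", upper = "matrix",
                 nsim = "integer", level = "numeric", pValue = "numeric",
                 pInterval = "numeric", erlRank = "numeric",
                 decision = "matrix"),
  validity = function(object) {
    if (any(object@lower > object@upper + 1e-12))
      return("lower envelope must not exceed upper envelope")
    TRUE
  })

## ---------------------------------------------------------------------------
## Validation containers
## ---------------------------------------------------------------------------

#' ConfusionCounts: TP / FP / TN / FN tallies
#'
#' @slot TP,FP,TN,FN non-negative counts (stored as doubles; pixel tallies
#'   can be large).
#' @export
setClass("ConfusionCounts",
  representation(TP = "numeric", FP = "numeric", TN = "numeric", FN = "numeric"),
  validity = function(object) {
    v <- c(object@TP, object@FP, object@TN, object@FN)
    if (any(v < 0) || any(!is.finite(v))) return("counts must be non-negative")
    TRUE
  })

#' @rdname ConfusionCounts-class
#' @param TP,FP,TN,FN counts.
#' @export
ConfusionCounts <- function(TP, FP = 0, TN = 0, FN = 0) {
  new("ConfusionCounts", TP = as.numeric(TP), FP = as.numeric(FP),
      TN = as.numeric(TN), FN = as.numeric(FN))
}

#' RigidTransform2D: an in-plane rotation plus translation
#'
#' Maps moving-image coordinates into the fixed frame by rotating by
#' `angle` degrees about the image centre and then translating by
#' (dx, dy) pixels, at full resolution.
#'
#' @slot angle rotation in degrees (counter-clockwise).
#' @slot dx,dy translation in pixels (row, column order follows dims 1, 2).
#' @slot converged FALSE when the optimizer failed and the identity was
#'   substituted.
#' @export
setClass("RigidTransform2D",
  representation(angle = "numeric", dx = "numeric", dy = "numeric",
                 converged = "logical"),
  prototype(converged = TRUE))

#' @rdname RigidTransform2D-class
#' @param angle,dx,dy,converged see slots.
#' @export
RigidTransform2D <- function(angle = 0, dx = 0, dy = 0, converged = TRUE) {
  new("RigidTransform2D", angle = as.numeric(angle), dx = as.numeric(dx),
      dy = as.numeric(dy), converged = converged)
}

#' SamplePlan: systematic biopsy placement on a tissue-block image
#'
#' @slot sampleMask binary matrix of the thresholded sample area.
#' @slot erodedMask sample area after disk erosion by the biopsy radius.
#' @slot quartileRows rows where cumulative white-pixel mass reaches
#'   25, 50 and 75 percent.
#' @slot chosenPoints 2 x 2 matrix of (row, col) biopsy centres.
#' @slot quarters the two quarters sampled (1 & 3 or 2 & 4).
#' @slot biopsyDiameter biopsy diameter in pixels.
#' @export
setClass("SamplePlan",
  representation(sampleMask = "matrix", erodedMask = "matrix",
                 quartileRows = "integer", chosenPoints = "matrix",
                 quarters = "integer", biopsyDiameter = "integer"))

#' SectionDetection: sections located on a slide montage
#'
#' @slot boxes data.frame with one row per detected section (reading order):
#'   r0, r1, c0, c1 bounding box, centroid row / col, area (px).
#' @slot masks list of binary matrices, cropped to each box.
#' @slot montageDim dimensions of the input montage.
#' @slot params detection parameters used.
#' @export
setClass("SectionDetection",
  representation(boxes = "data.frame", masks = "list",
                 montageDim = "integer", params = "list"))

#' LayerWindow: the layer III analysis interval along the pial axis
#'
#' @slot bounds (lo, hi) in um along the x-axis.
#' @slot mode "auto" (density-based) or "manual".
#' @slot peaks positions of the flanking density peaks (auto mode).
#' @export
setClass("LayerWindow",
  representation(bounds = "numeric", mode = "character", peaks = "numeric"),
  validity = function(object) {
    if (length(object@bounds) != 2 || object@bounds[1] >= object@bounds[2])
      return("bounds must be (lo, hi) with lo < hi")
    TRUE
  })

#' SyntheticScene: a rendered synthetic tissue volume with ground truth
#'
#' @slot params the [sceneParams()] list used.
#' @slot cells data.frame of ground-truth cells (centroid, semi-axes,
#'   orientation, class, analytic volume / sphericity).
#' @slot pattern the [PointPattern3D-class] of cell centroids.
#' @slot stack rendered [ImageStack-class].
#' @slot truthLabels ground-truth [LabelVolume-class].
#' @slot notes character vector of generation warnings (e.g. overlap).
#' @export
setClass("SyntheticScene",
  representation(params = "list", cells = "data.frame",
                 pattern = "PointPattern3D", stack = "ImageStack",
                 truthLabels = "LabelVolume", notes = "character"))

## ---------------------------------------------------------------------------
## Generics and accessors
## ---------------------------------------------------------------------------

#' @rdname accessors
#' @param x an object with voxel data.
#' @export
setGeneric("stackData", function(x) standardGeneric("stackData"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("stackOrigin", function(x) standardGeneric("stackOrigin"))

#' Accessors for voxel containers and point patterns
#'
#' @name accessors
#' @return `stackData` the raw array; `voxelSpacing` / `stackOrigin` numeric
#'   length-3 vectors; `npoints` the number of points; `patternWindow` the
#'   2 x 3 window matrix; `patternIntensity` the estimated intensity n/|W|
#'   in points per cubic micrometre.
NULL

for (cl in c("ImageStack", "MaskStack", "LabelVolume")) {
  setMethod("stackData", cl, function(x) x@data)
  setMethod("voxelSpacing", cl, function(x) x@spacing)
  setMethod("stackOrigin", cl, function(x) x@origin)
  setMethod("dim", cl, function(x) dim(x@data))
}

#' @rdname accessors
#' @export
setGeneric("npoints", function(x) standardGeneric("npoints"))
setMethod("npoints", "PointPattern3D", function(x) nrow(x@coords))

#' @rdname accessors
#' @export
setGeneric("patternCoords", function(x) standardGeneric("patternCoords"))
setMethod("patternCoords", "PointPattern3D", function(x) x@coords)

#' @rdname accessors
#' @export
setGeneric("patternWindow", function(x) standardGeneric("patternWindow"))
setMethod("patternWindow", "PointPattern3D", function(x) x@window)

#' @rdname accessors
#' @export
setGeneric("patternMarks", function(x) standardGeneric("patternMarks"))
setMethod("patternMarks", "PointPattern3D", function(x) x@marks)

#' @rdname accessors
#' @export
setGeneric("patternIntensity", function(x) standardGeneric("patternIntensity"))
setMethod("patternIntensity", "PointPattern3D", function(x) {
  nrow(x@coords) / prod(x@window[2, ] - x@window[1, ])
})

#' @rdname accessors
#' @export
windowVolume <- function(x) prod(patternWindow(x)[2, ] - patternWindow(x)[1, ])

#' @rdname accessors
#' @param object object to display.
#' @export
setGeneric("confusionVector", function(x) standardGeneric("confusionVector"))
setMethod("confusionVector", "ConfusionCounts", function(x) {
  c(TP = x@TP, FP = x@FP, TN = x@TN, FN = x@FN)
})

## show methods -------------------------------------------------------------

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageStack %d x %d x %d voxels, spacing (%.3g, %.3g, %.3g) um\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  cat(sprintf("  intensity range [%.3g, %.3g]\n", min(object@data),
              max(object@data)))
})

setMethod("show", "MaskStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("MaskStack %d x %d x %d voxels, %.2f%% foreground\n",
              d[1], d[2], d[3], 100 * mean(object@data)))
})

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("LabelVolume %d x %d x %d voxels, %d objects (%d edge-flagged)\n",
              d[1], d[2], d[3], max(object@data), length(object@edgeLabels)))
})

setMethod("show", "PointPattern3D", function(object) {
  w <- object@window
  cat(sprintf("PointPattern3D: %d points in [%g, %g] x [%g, %g] x [%g, %g] um\n",
              nrow(object@coords), w[1, 1], w[2, 1], w[1, 2], w[2, 2],
              w[1, 3], w[2, 3]))
  cat(sprintf("  intensity %.4g um^-3 (%.0f mm^-3)\n",
              patternIntensity(object), patternIntensity(object) * 1e9))
})

setMethod("show", "CylKEstimate", function(object) {
  cat(sprintf("Cylindrical K estimate, direction (%.2f, %.2f, %.2f)\n",
              object@direction[1], object@direction[2], object@direction[3]))
  cat(sprintf("  grid %d r-values in [%g, %g] x %d t-values in [%g, %g], n = %d\n",
              length(object@r), min(object@r), max(object@r),
              length(object@t), min(object@t), max(object@t), object@n))
})

setMethod("show", "GlobalEnvelope", function(object) {
  cat(sprintf("ERL global envelope test (%d%% level, %d simulations)\n",
              round(100 * object@level), object@nsim))
  cat(sprintf("  p = %.4g  (interval %.4g - %.4g), observed ERL rank %d\n",
              object@pValue, object@pInterval[1], object@pInterval[2],
              object@erlRank))
  tab <- table(factor(object@decision, levels = c("below", "inside", "above")))
  cat(sprintf("  grid cells: %d below, %d inside, %d above\n",
              tab["below"], tab["inside"], tab["above"]))
})

setMethod("show", "ConfusionCounts", function(object) {
  cat("ConfusionCounts:", paste(names(confusionVector(object)),
                                confusionVector(object), sep = "=",
                                collapse = " "), "\n")
})

setMethod("show", "SyntheticScene", function(object) {
  cat(sprintf("SyntheticScene: %d cells (%d pyramidal, %d small round)\n",
              nrow(object@cells), sum(object@cells$class == "pyramidal"),
              sum(object@cells$class == "small_round")))
  show(object@stack)
  if (length(object@notes)) cat("  notes:", paste(object@notes, collapse = "; "), "\n")
})

setMethod("show", "LayerWindow", function(object) {
  cat(sprintf("LayerWindow [%.1f, %.1f] um (%s)\n", object@bounds[1],
              object@bounds[2], object@mode))
})

setMethod("show", "RigidTransform2D", function(object) {
  cat(sprintf("RigidTransform2D: angle %.3f deg, shift (%.2f, %.2f) px%s\n",
              object@angle, object@dx, object@dy,
              if (object@converged) "" else " [not converged]"))
})
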