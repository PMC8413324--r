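## Synthetic scenes: columnar / CSR point patterns, ellipsoidal cells, and
## rendered image stacks emulating toluidine-blue semi-thin sections.

#' Scene parameters for the synthetic-data generator
#'
#' Bundles every knob of the generator with defaults chosen to emulate layer
#' III of human dorsolateral prefrontal cortex: pyramidal-cell number density
#' 28,155 mm^-3 arranged in cylindrical columns along the x-axis (which
#' points toward the pial surface), mean cell volume 795 um^3, mean folded
#' orientation close to 29 degrees, plus a contingent of small round cells
#' (glia / non-pyramidal neurons) to exercise the classifier.
#'
#' `columnIntensity` (columns per um^2 of the y-z plane) defaults to the
#' value that yields `targetDensity` for pyramidal cells before hardcore
#' thinning: intensity = targetDensity * Lx / pointsPerColumnMean.
#'
#' @param windowBox box dimensions (Lx, Ly, Lz) in um.
#' @param targetDensity nominal pyramidal-cell density in mm^-3 used to
#'   derive `columnIntensity` when that is NULL.
#' @param columnIntensity columns per um^2 in the y-z plane (NULL = derived).
#' @param pointsPerColumnMean mean points per column (Poisson).
#' @param columnRadiusSD radial Gaussian displacement scale within a column
#'   (um).
#' @param hardcoreDistance minimum allowed pairwise centroid distance (um);
#'   0 disables point-level thinning.  The default relies on the cell-level
#'   non-overlap constraint instead (`excludeOverlaps`).
#' @param excludeOverlaps treat somata as impenetrable: cells whose
#'   ellipsoids would interpenetrate an already placed cell are redrawn at
#'   another position in their column (dropped after 20 failed tries).
#' @param cellVolumeMean,cellVolumeLogSD log-normal volume model for
#'   pyramidal cells: mean volume in um^3 and the SD of log-volume.
#' @param targetSphericityMean,targetSphericitySD analytic spheroid
#'   sphericity targets for pyramidal cells (dimensionless).
#' @param orientationConcentration folded-normal scale (degrees) of the
#'   orientation angle about the x-axis; 0 aligns every cell with x.
#' @param smallRoundFraction fraction of points emitted as small round
#'   (non-pyramidal) cells.
#' @param smallRoundVolumeMean,smallRoundVolumeLogSD log-normal volume model
#'   for the small round class (um^3).
#' @param voxelSpacing voxel spacing (dx, dy, dz) in um.
#' @param psfSigma Gaussian point-spread sigma in um.
#' @param noiseSD additive Gaussian noise SD (intensity units).
#' @param backgroundLevel,cellLevel background and cell intensity levels
#'   (cells are darker than background, as in toluidine-blue stains).
#' @param overlapWarnFraction per-cell voxel overlap fraction above which a
#'   warning is recorded in the scene notes.
#' @param seed integer seed; NULL uses the current RNG state.
#' @return a named list of validated parameters.
#' @export
sceneParams <- function(windowBox = c(200, 200, 90),
                        targetDensity = 28155,
                        columnIntensity = NULL,
                        pointsPerColumnMean = 6,
                        columnRadiusSD = 10,
                        hardcoreDistance = 0,
                        excludeOverlaps = TRUE,
                        cellVolumeMean = 795,
                        cellVolumeLogSD = 0.45,
                        targetSphericityMean = 0.85,
                        targetSphericitySD = 0.03,
                        orientationConcentration = 36,
                        smallRoundFraction = 0.25,
                        smallRoundVolumeMean = 120,
                        smallRoundVolumeLogSD = 0.35,
                        voxelSpacing = c(0.5, 0.5, 0.9),
                        psfSigma = 0.4,
                        noiseSD = 8,
                        backgroundLevel = 200,
                        cellLevel = 60,
                        overlapWarnFraction = 0.15,
                        seed = NULL) {
  if (length(windowBox) != 3 || any(!is.finite(windowBox)) || any(windowBox <= 0))
    stop("degenerate window: all box sides must be strictly positive")
  if (any(voxelSpacing <= 0)) stop("voxel spacing must be strictly positive")
  if (is.null(columnIntensity)) {
    ## derived so that the PYRAMIDAL intensity hits targetDensity before
    ## hardcore thinning; the small-round contingent rides on top
    columnIntensity <- targetDensity * 1e-9 * windowBox[1] /
      (pointsPerColumnMean * (1 - smallRoundFraction))
  }
  p <- list(windowBox = as.numeric(windowBox),
            columnIntensity = columnIntensity,
            pointsPerColumnMean = pointsPerColumnMean,
            columnRadiusSD = columnRadiusSD,
            hardcoreDistance = hardcoreDistance,
            excludeOverlaps = excludeOverlaps,
            cellVolumeMean = cellVolumeMean,
            cellVolumeLogSD = cellVolumeLogSD,
            targetSphericityMean = targetSphericityMean,
            targetSphericitySD = targetSphericitySD,
            orientationConcentration = orientationConcentration,
            smallRoundFraction = smallRoundFraction,
            smallRoundVolumeMean = smallRoundVolumeMean,
            smallRoundVolumeLogSD = smallRoundVolumeLogSD,
            voxelSpacing = as.numeric(voxelSpacing),
            psfSigma = psfSigma, noiseSD = noiseSD,
            backgroundLevel = backgroundLevel, cellLevel = cellLevel,
            overlapWarnFraction = overlapWarnFraction,
            seed = seed)
  p
}

#' Simulate a columnar (Poisson cylinder-cluster) point pattern
#'
#' Poisson column centres in the y-z plane, a Poisson number of points per
#' column, x uniform over the whole window (columns traverse the full
#' height), Gaussian radial displacement in (y, z) wrapped periodically into
#' the window, followed by optional sequential hardcore thinning (a point is
#' kept only if at least `hardcoreDistance` from every previously kept
#' point, in generation order).
#'
#' @param params a [sceneParams()] list.
#' @param seed overrides `params$seed` when non-NULL.
#' @return a [PointPattern3D-class] with a `column` mark.
#' @export
simulateColumnarPattern <- function(params = sceneParams(), seed = NULL) {
  seed <- seed %||% params$seed
  .withSeed(seed, {
    W <- params$windowBox
    if (any(W <= 0)) stop("degenerate window: all box sides must be strictly positive")
    nCol <- stats::rpois(1, params$columnIntensity * W[2] * W[3])
    if (nCol == 0 || params$columnIntensity == 0) {
      return(PointPattern3D(matrix(numeric(), 0, 3), W,
                            marks = data.frame(column = integer())))
    }
    cy <- stats::runif(nCol, 0, W[2])
    cz <- stats::runif(nCol, 0, W[3])
    nPts <- stats::rpois(nCol, params$pointsPerColumnMean)
    col <- rep.int(seq_len(nCol), nPts)
    n <- sum(nPts)
    if (n == 0) {
      return(PointPattern3D(matrix(numeric(), 0, 3), W,
                            marks = data.frame(column = integer())))
    }
    x <- stats::runif(n, 0, W[1])
    y <- (cy[col] + stats::rnorm(n, 0, params$columnRadiusSD)) %% W[2]
    z <- (cz[col] + stats::rnorm(n, 0, params$columnRadiusSD)) %% W[3]
    pts <- cbind(x, y, z)
    keep <- .hardcoreThin(pts, params$hardcoreDistance)
    PointPattern3D(pts[keep, , drop = FALSE], W,
                   marks = data.frame(column = col[keep]))
  })
}

## Sequential dependent thinning: keep a point iff >= d from all kept points.
.hardcoreThin <- function(pts, d) {
  n <- nrow(pts)
  if (d <= 0 || n < 2) return(rep(TRUE, n))
  keep <- logical(n)
  keptIdx <- integer(0)
  d2 <- d * d
  for (i in seq_len(n)) {
    if (length(keptIdx)) {
      dd <- (pts[keptIdx, 1] - pts[i, 1])^2 +
            (pts[keptIdx, 2] - pts[i, 2])^2 +
            (pts[keptIdx, 3] - pts[i, 3])^2
      if (min(dd) < d2) next
    }
    keep[i] <- TRUE
    keptIdx <- c(keptIdx, i)
  }
  keep
}

#' Simulate complete spatial randomness in a box
#'
#' Binomial variant (fixed n, points i.i.d. uniform) or Poisson variant
#' (n drawn as Poisson(intensity * |W|)).
#'
#' @param n fixed number of points (binomial variant).
#' @param intensity points per um^3 (Poisson variant; used when `n` is NULL).
#' @param windowBox (Lx, Ly, Lz) in um, or a 2 x 3 bounds matrix.
#' @param seed integer seed or NULL.
#' @return a [PointPattern3D-class].
#' @export
simulateCSRPattern <- function(n = NULL, intensity = NULL,
                               windowBox = c(100, 100, 100), seed = NULL) {
  if (is.null(n) && is.null(intensity))
    stop("supply either 'n' or 'intensity'")
  if (!is.null(n) && n < 0) stop("'n' must be non-negative")
  if (!is.null(intensity) && intensity < 0)
    stop("'intensity' must be non-negative")
  if (is.null(dim(windowBox))) {
    lo <- c(0, 0, 0); hi <- as.numeric(windowBox)
  } else {
    lo <- windowBox[1, ]; hi <- windowBox[2, ]
  }
  if (any(hi <= lo)) stop("degenerate window: all box sides must be strictly positive")
  .withSeed(seed, {
    if (is.null(n)) n <- stats::rpois(1, intensity * prod(hi - lo))
    pts <- cbind(stats::runif(n, lo[1], hi[1]),
                 stats::runif(n, lo[2], hi[2]),
                 stats::runif(n, lo[3], hi[3]))
    PointPattern3D(pts, rbind(lo = lo, hi = hi))
  })
}

## --- spheroid geometry ------------------------------------------------------

#' Surface area of a spheroid with semi-axes (a, b, b)
#'
#' Closed form for prolate (a > b), oblate (a < b) and spherical (a = b)
#' cases.
#'
#' @param a polar semi-axis (um).
#' @param b equatorial semi-axis (um).
#' @return surface area in um^2.
#' @export
spheroidSurfaceArea <- function(a, b) {
  mapply(function(a, b) {
    if (abs(a - b) < 1e-12 * max(a, b)) return(4 * pi * a^2)
    if (a > b) { # prolate
      e <- sqrt(1 - (b / a)^2)
      2 * pi * b^2 * (1 + (a / (b * e)) * asin(e))
    } else {     # oblate
      e <- sqrt(1 - (a / b)^2)
      2 * pi * b^2 + pi * a^2 / e * log((1 + e) / (1 - e))
    }
  }, a, b)
}

#' Analytic sphericity of a spheroid with aspect ratio k = a/b
#'
#' Sphericity is pi^(1/3) (6V)^(2/3) / A; for a spheroid it depends only on
#' the aspect ratio.
#'
#' @param aspect ratio a/b (>= 0, 1 = sphere).
#' @return sphericity in (0, 1].
#' @export
spheroidSphericity <- function(aspect) {
  vapply(aspect, function(k) {
    b <- 1; a <- k
    V <- 4 / 3 * pi * a * b^2
    A <- spheroidSurfaceArea(a, b)
    pi^(1 / 3) * (6 * V)^(2 / 3) / A
  }, numeric(1))
}

## Invert sphericity -> prolate aspect ratio (a/b >= 1).
.aspectForSphericity <- function(psi) {
  if (psi > 1 + 1e-9) stop("unsatisfiable sphericity target: must be <= 1")
  if (psi >= 1 - 1e-9) return(1)
  f <- function(lk) spheroidSphericity(exp(lk)) - psi
  exp(stats::uniroot(f, c(0, log(1e4)), tol = 1e-10)$root)
}

#' Draw ellipsoidal ground-truth cells on a point pattern
#'
#' Pyramidal cells are prolate spheroids: volumes are log-normal with the
#' configured mean, the aspect ratio is solved in closed form so the
#' analytic spheroid sphericity matches the drawn target, and the long axis
#' direction follows a folded-normal angle about the x-axis with uniform
#' azimuth.  A fraction of cells is emitted as small round cells (spheres
#' with a smaller volume scale) to exercise the downstream classifier.
#'
#' @param pattern a [PointPattern3D-class] of cell centroids.
#' @param params a [sceneParams()] list.
#' @param seed overrides `params$seed` when non-NULL.
#' @return data.frame with one row per cell: id, centroid, semi-axes
#'   (a >= b = c), orientation unit vector, class, analytic volume and
#'   sphericity.
#' @export
synthesizeCells <- function(pattern, params = sceneParams(), seed = NULL) {
  n <- npoints(pattern)
  if (n == 0) stop("pattern is empty; nothing to synthesize")
  if (params$targetSphericityMean > 1)
    stop("unsatisfiable sphericity target: must be <= 1")
  seed <- seed %||% params$seed
  .withSeed(if (is.null(seed)) NULL else .childSeed(seed, 1), {
    xyz <- patternCoords(pattern)
    isSmall <- stats::runif(n) < params$smallRoundFraction
    mu <- log(params$cellVolumeMean) - params$cellVolumeLogSD^2 / 2
    muS <- log(params$smallRoundVolumeMean) - params$smallRoundVolumeLogSD^2 / 2
    vol <- ifelse(isSmall,
                  stats::rlnorm(n, muS, params$smallRoundVolumeLogSD),
                  stats::rlnorm(n, mu, params$cellVolumeLogSD))
    psi <- pmin(1, pmax(0.05, stats::rnorm(n, params$targetSphericityMean,
                                           params$targetSphericitySD)))
    psi[isSmall] <- 1
    aspect <- vapply(psi, .aspectForSphericity, numeric(1))
    b <- (3 * vol / (4 * pi * aspect))^(1 / 3)
    a <- aspect * b
    if (params$orientationConcentration > 0) {
      theta <- abs(stats::rnorm(n, 0, params$orientationConcentration)) %% 180
      theta <- ifelse(theta > 90, 180 - theta, theta)
    } else theta <- rep(0, n)
    theta[isSmall] <- 0
    phi <- stats::runif(n, 0, 2 * pi)
    th <- theta * pi / 180
    u <- cbind(cos(th), sin(th) * cos(phi), sin(th) * sin(phi))
    mk <- patternMarks(pattern)
    cells <- data.frame(id = seq_len(n),
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               a = a, b = b, c = b,
               ux = u[, 1], uy = u[, 2], uz = u[, 3],
               volume = vol, sphericity = psi, thetaDeg = theta,
               class = ifelse(isSmall, "small_round", "pyramidal"),
               column = if ("column" %in% names(mk)) mk$column else NA_integer_)
    if (isTRUE(params$excludeOverlaps))
      cells <- .resolveOverlaps(cells, pattern, params)
    cells
  })
}

## Somata are impenetrable: place cells sequentially and redraw the position
## of any cell whose ellipsoid would interpenetrate an already placed one
## (new x, new radial offset about its own column centre), dropping it after
## `maxRetry` failed attempts.  The overlap proxy is the axis-aligned
## summed-semi-axis test, conservative for the mostly x-aligned cells here.
.resolveOverlaps <- function(cells, pattern, params, maxRetry = 20) {
  n <- nrow(cells)
  if (n < 2) return(cells)
  W <- params$windowBox
  mk <- patternMarks(pattern)
  colCtr <- NULL
  if ("column" %in% names(mk) && nrow(mk) && !all(is.na(cells$column))) {
    ## column centres recovered as the per-column mean of (y, z)
    xyz <- patternCoords(pattern)
    colCtr <- cbind(tapply(xyz[, 2], mk$column, mean),
                    tapply(xyz[, 3], mk$column, mean))
  }
  ## per-cell extent along each axis: sqrt(a^2 (u.e)^2 + b^2 (1 - (u.e)^2)),
  ## plus a thin neuropil gap; the test over-covers tilted cells, so it is
  ## conservative
  gap <- 0.5
  extOf <- function(idx) {
    u2 <- cbind(cells$ux[idx], cells$uy[idx], cells$uz[idx])^2
    sqrt(cells$a[idx]^2 * u2 + cells$b[idx]^2 * (1 - u2)) + gap
  }
  ext <- extOf(seq_len(n))
  overlaps <- function(q, keptIdx) {
    dx <- cells$x[keptIdx] - cells$x[q]
    dy <- cells$y[keptIdx] - cells$y[q]
    dz <- cells$z[keptIdx] - cells$z[q]
    sx <- ext[keptIdx, 1] + ext[q, 1]
    sy <- ext[keptIdx, 2] + ext[q, 2]
    sz <- ext[keptIdx, 3] + ext[q, 3]
    any((dx / sx)^2 + (dy / sy)^2 + (dz / sz)^2 < 1)
  }
  kept <- 1L
  drop <- logical(n)
  for (q in 2:n) {
    tries <- 0
    while (overlaps(q, kept) && tries < maxRetry) {
      tries <- tries + 1
      cells$x[q] <- stats::runif(1, 0, W[1])
      if (!is.null(colCtr) && !is.na(cells$column[q])) {
        ctr <- colCtr[as.character(cells$column[q]), ]
        cells$y[q] <- (ctr[1] + stats::rnorm(1, 0, params$columnRadiusSD)) %% W[2]
        cells$z[q] <- (ctr[2] + stats::rnorm(1, 0, params$columnRadiusSD)) %% W[3]
      } else {
        cells$y[q] <- stats::runif(1, 0, W[2])
        cells$z[q] <- stats::runif(1, 0, W[3])
      }
    }
    if (tries >= maxRetry && overlaps(q, kept)) drop[q] <- TRUE
    else kept <- c(kept, q)
  }
  cells <- cells[!drop, , drop = FALSE]
  cells$id <- seq_len(nrow(cells))
  rownames(cells) <- NULL
  cells
}

#' Render a synthetic image stack (plus ground-truth labels) from cells
#'
#' Cells are voxelised on the anisotropic grid (a voxel belongs to the
#' nearest cell whose ellipsoid contains its centre; ties go to the lower
#' id).  The intensity stack is background with darker cell voxels,
#' convolved with a Gaussian point-spread function and degraded with
#' additive Gaussian noise.  The stack extends beyond the observation window
#' by a pad sufficient to contain every cell, so cells near the window
#' boundary are rendered in full; `stackOrigin()` records the offset.
#'
#' @param cells data.frame from [synthesizeCells()].
#' @param params a [sceneParams()] list.
#' @param pattern optional original [PointPattern3D-class] stored in the
#'   scene (reconstructed from `cells` when NULL).
#' @param seed overrides `params$seed` when non-NULL.
#' @return a [SyntheticScene-class].
#' @export
renderStack <- function(cells, params = sceneParams(), pattern = NULL,
                        seed = NULL) {
  sp <- params$voxelSpacing
  if (any(sp <= 0)) stop("voxel spacing must be strictly positive")
  W <- params$windowBox
  seed <- seed %||% params$seed
  pad <- max(cells$a) + 2 * params$psfSigma + 2 * max(sp)
  lo <- -rep(pad, 3)
  hi <- W + pad
  dims <- as.integer(ceiling((hi - lo) / sp))
  labels <- array(0L, dims)
  bestd <- array(Inf, dims)
  notes <- character()
  axc <- lapply(1:3, function(d) lo[d] + (seq_len(dims[d]) - 0.5) * sp[d])
  counts <- integer(nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    ctr <- c(cells$x[ci], cells$y[ci], cells$z[ci])
    amax <- cells$a[ci]
    rng <- lapply(1:3, function(d) {
      which(axc[[d]] >= ctr[d] - amax & axc[[d]] <= ctr[d] + amax)
    })
    if (any(lengths(rng) == 0)) next
    gx <- axc[[1]][rng[[1]]] - ctr[1]
    gy <- axc[[2]][rng[[2]]] - ctr[2]
    gz <- axc[[3]][rng[[3]]] - ctr[3]
    u <- c(cells$ux[ci], cells$uy[ci], cells$uz[ci])
    ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- c(u[2] * ref[3] - u[3] * ref[2],
           u[3] * ref[1] - u[1] * ref[3],
           u[1] * ref[2] - u[2] * ref[1])
    v <- v / sqrt(sum(v^2))
    w <- c(u[2] * v[3] - u[3] * v[2],
           u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
    nx <- length(gx); ny <- length(gy); nz <- length(gz)
    X <- array(gx, c(nx, ny, nz))
    Y <- array(rep(gy, each = nx), c(nx, ny, nz))
    Z <- array(rep(gz, each = nx * ny), c(nx, ny, nz))
    pu <- X * u[1] + Y * u[2] + Z * u[3]
    pv <- X * v[1] + Y * v[2] + Z * v[3]
    pw <- X * w[1] + Y * w[2] + Z * w[3]
    inside <- (pu / cells$a[ci])^2 + (pv / cells$b[ci])^2 +
              (pw / cells$c[ci])^2 <= 1
    if (!any(inside)) next
    d2 <- X^2 + Y^2 + Z^2
    sub <- labels[rng[[1]], rng[[2]], rng[[3]]]
    subd <- bestd[rng[[1]], rng[[2]], rng[[3]]]
    contested <- inside & sub > 0L
    take <- inside & (d2 < subd)   # strict: ties keep the earlier (lower) id
    sub[take] <- cells$id[ci]
    subd[take] <- d2[take]
    labels[rng[[1]], rng[[2]], rng[[3]]] <- sub
    bestd[rng[[1]], rng[[2]], rng[[3]]] <- subd
    counts[ci] <- sum(inside)
    if (sum(contested) > params$overlapWarnFraction * sum(inside)) {
      notes <- c(notes, sprintf(
        "cell %d overlaps neighbours on %.0f%% of its voxels",
        cells$id[ci], 100 * sum(contested) / sum(inside)))
    }
  }
  rm(bestd)
  img <- params$backgroundLevel +
    (params$cellLevel - params$backgroundLevel) * (labels > 0L)
  if (params$psfSigma > 0) img <- .gaussianSmooth(img, params$psfSigma / sp)
  if (params$noiseSD > 0) {
    img <- img + .withSeed(if (is.null(seed)) NULL else .childSeed(seed, 2),
                           stats::rnorm(length(img), 0, params$noiseSD))
    dim(img) <- dims
  }
  cells$voxelCount <- tabulate(labels, nbins = nrow(cells))
  if (is.null(pattern)) {
    pattern <- PointPattern3D(as.matrix(cells[, c("x", "y", "z")]), W,
                              marks = cells[, c("class", "column")])
  }
  new("SyntheticScene", params = params, cells = cells, pattern = pattern,
      stack = ImageStack(img, sp, origin = lo),
      truthLabels = LabelVolume(labels, sp, origin = lo,
                                edgeLabels = integer()),
      notes = notes)
}

#' Generate a complete synthetic scene
#'
#' Convenience wrapper: columnar pattern, cell synthesis, stack rendering.
#'
#' @param params a [sceneParams()] list.
#' @param seed overrides `params$seed` when non-NULL.
#' @return a [SyntheticScene-class].
#' @export
simulateScene <- function(params = sceneParams(), seed = NULL) {
  seed <- seed %||% params$seed
  pat <- simulateColumnarPattern(params, seed = seed)
  cells <- synthesizeCells(pat, params, seed = seed)
  ## the non-overlap constraint may reposition cells, so the stored pattern
  ## is rebuilt from the final cell centroids
  renderStack(cells, params, seed = seed)
}
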