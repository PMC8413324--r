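## Pre-analysis image plumbing: systematic biopsy placement on a tissue
## block, entropy-based section detection on slide montages, and sequential
## rigid slice-to-slice alignment.

## --- biopsy planning --------------------------------------------------------

#' Plan two systematic biopsy positions on a tissue-block image
#'
#' The image is binarised inside the region of interest with a global
#' (Otsu) threshold, the sample area is eroded with a disk structuring
#' element whose diameter equals the biopsy diameter (so a punch never
#' straddles the boundary), the area is divided into four quarters by the
#' rows at which the cumulative white-pixel count reaches 25, 50 and 75
#' percent, and one seeded uniform pick is drawn from each of two
#' non-adjacent quarters (1 & 3 or 2 & 4, the pair itself seeded).
#'
#' @param image 2D grayscale matrix (or 3D array whose channels are
#'   averaged).
#' @param roiPolygon m x 2 matrix of (row, col) vertices delineating the
#'   region of interest.
#' @param biopsyDiameterPx biopsy diameter in pixels (>= 1).
#' @param seed integer seed.
#' @param tissue "bright" when tissue is brighter than background inside
#'   the ROI, "dark" otherwise.
#' @return a [SamplePlan-class].
#' @export
planBiopsies <- function(image, roiPolygon, biopsyDiameterPx, seed = NULL,
                         tissue = c("bright", "dark")) {
  tissue <- match.arg(tissue)
  if (length(dim(image)) == 3) image <- apply(image, c(1, 2), mean)
  if (biopsyDiameterPx < 1) stop("biopsy diameter must be at least 1 px")
  roiPolygon <- as.matrix(roiPolygon)
  if (nrow(unique(roiPolygon)) < 3) stop("degenerate ROI polygon")
  d <- dim(image)
  px <- cbind(rep(seq_len(d[1]), d[2]), rep(seq_len(d[2]), each = d[1]))
  inside <- matrix(.pointsInPolygon(px, roiPolygon), d[1], d[2])
  if (!any(inside)) stop("ROI polygon covers no pixels")
  thr <- .otsu(image[inside])
  tissueMask <- if (tissue == "bright") image >= thr else image < thr
  sampleMask <- (inside & tissueMask) * 1
  r <- floor(biopsyDiameterPx / 2)
  eroded <- if (r >= 1) {
    ## Euclidean disk structuring element of radius = biopsy radius
    kern <- (outer((-r:r)^2, (-r:r)^2, "+") <= r^2) * 1
    EBImage::erode(sampleMask, kern)
  } else sampleMask
  if (!any(eroded > 0))
    stop("sample area too small for biopsy diameter")
  rs <- rowSums(sampleMask)
  cs <- cumsum(rs)
  total <- cs[length(cs)]
  qr <- vapply(c(0.25, 0.5, 0.75),
               function(f) which(cs >= f * total)[1], integer(1))
  quarterOf <- findInterval(seq_len(d[1]), qr + 1L) + 1L  # 1..4 by row
  .withSeed(seed, {
    cand <- lapply(1:4, function(q) {
      which(eroded > 0 & matrix(quarterOf == q, d[1], d[2]), arr.ind = TRUE)
    })
    ok13 <- nrow(cand[[1]]) > 0 && nrow(cand[[3]]) > 0
    ok24 <- nrow(cand[[2]]) > 0 && nrow(cand[[4]]) > 0
    pair <- if (ok13 && ok24) {
      if (stats::runif(1) < 0.5) c(1L, 3L) else c(2L, 4L)
    } else if (ok13) c(1L, 3L) else if (ok24) c(2L, 4L) else
      stop("sample area too small for biopsy diameter")
    pts <- matrix(NA_real_, 2, 2, dimnames = list(NULL, c("row", "col")))
    for (q in seq_along(pair)) {
      cq <- cand[[pair[q]]]
      pts[q, ] <- cq[sample.int(nrow(cq), 1), ]
    }
    new("SamplePlan", sampleMask = sampleMask,
        erodedMask = matrix(as.numeric(eroded > 0), d[1], d[2]),
        quartileRows = qr, chosenPoints = pts, quarters = pair,
        biopsyDiameter = as.integer(biopsyDiameterPx))
  })
}

## --- section detection ------------------------------------------------------

## local entropy of a grayscale image over a square window, histogram with
## `nbins` bins of the global range; exact box sums via integral images.
.localEntropy <- function(img, window = 9, nbins = 16) {
  rng <- range(img)
  if (diff(rng) <= 0) return(matrix(0, nrow(img), ncol(img)))
  b <- pmin(nbins, 1L + floor((img - rng[1]) / diff(rng) * nbins))
  dim(b) <- dim(img)
  r <- (window - 1) %/% 2
  d <- dim(img)
  counts <- vector("list", nbins)
  boxSum <- function(m, r) {
    cs <- apply(apply(m, 2, cumsum), 1, cumsum) # transposed integral image
    cs <- t(cs)
    n1 <- nrow(m); n2 <- ncol(m)
    i0 <- pmax(seq_len(n1) - r - 1L, 0L); i1 <- pmin(seq_len(n1) + r, n1)
    j0 <- pmax(seq_len(n2) - r - 1L, 0L); j1 <- pmin(seq_len(n2) + r, n2)
    csp <- rbind(0, cbind(0, cs))
    csp[i1 + 1L, j1 + 1L] - csp[i0 + 1L, j1 + 1L] -
      csp[i1 + 1L, j0 + 1L] + csp[i0 + 1L, j0 + 1L]
  }
  tot <- boxSum(matrix(1, d[1], d[2]), r)
  H <- matrix(0, d[1], d[2])
  for (k in seq_len(nbins)) {
    ck <- boxSum((b == k) * 1, r)
    p <- ck / tot
    lp <- ifelse(p > 0, log2(p), 0)
    H <- H - p * lp
  }
  H
}

#' Detect tissue sections on a slide montage
#'
#' Grayscale montage -> Gaussian blur -> local-entropy map (sections carry
#' fine detail; empty tape is flat) -> global threshold -> removal of small
#' components -> one bounding box and mask per surviving component, ordered
#' for section numbering (bottom-right to top-left by default).  Supports
#' systematic sampling of every k-th detected section.
#'
#' @param montage 2D grayscale matrix.
#' @param blurSigma Gaussian blur sigma (px) before the entropy filter.
#' @param entropyWindow odd window size (px) of the entropy filter.
#' @param threshold entropy threshold; NULL uses Otsu on the entropy map.
#' @param minArea minimum component area in px.
#' @param everyK keep every k-th section (systematic sampling).
#' @param order reading order for numbering.
#' @return a [SectionDetection-class]; zero detected sections yields an
#'   empty result with a warning.
#' @export
detectSections <- function(montage, blurSigma = 2, entropyWindow = 9,
                           threshold = NULL, minArea = 500, everyK = 1,
                           order = c("bottomright-topleft",
                                     "topleft-bottomright")) {
  order <- match.arg(order)
  if (!length(montage)) stop("empty montage")
  sm <- if (blurSigma > 0) .gaussianSmooth2D(montage, blurSigma) else montage
  H <- .localEntropy(sm, window = entropyWindow)
  params <- list(blurSigma = blurSigma, entropyWindow = entropyWindow,
                 minArea = minArea, everyK = everyK, order = order)
  emptyResult <- function() {
    warning("no sections detected")
    new("SectionDetection", boxes = data.frame(), masks = list(),
        montageDim = dim(montage), params = params)
  }
  if (diff(range(H)) < 1e-8) return(emptyResult())
  if (is.null(threshold)) threshold <- .otsu(as.vector(H))
  bin <- (H > threshold) * 1
  lab <- EBImage::bwlabel(bin)
  nlab <- max(lab)
  if (nlab == 0) return(emptyResult())
  areas <- tabulate(lab[lab > 0], nlab)
  keep <- which(areas >= minArea)
  if (!length(keep)) return(emptyResult())
  info <- lapply(keep, function(L) {
    idx <- which(lab == L, arr.ind = TRUE)
    data.frame(label = L, r0 = min(idx[, 1]), r1 = max(idx[, 1]),
               c0 = min(idx[, 2]), c1 = max(idx[, 2]),
               crow = mean(idx[, 1]), ccol = mean(idx[, 2]),
               area = nrow(idx))
  })
  boxes <- do.call(rbind, info)
  ## group into shelf rows, then order within rows
  hmed <- stats::median(boxes$r1 - boxes$r0 + 1)
  o <- order(boxes$crow, decreasing = TRUE)
  rowId <- integer(nrow(boxes))
  cur <- 0; ref <- -Inf
  for (q in o) {
    if (abs(boxes$crow[q] - ref) > 0.6 * hmed) {
      cur <- cur + 1; ref <- boxes$crow[q]
    }
    rowId[q] <- cur
  }
  ord <- order(rowId, -boxes$ccol)
  if (order == "topleft-bottomright") ord <- rev(ord)
  boxes <- boxes[ord, , drop = FALSE]
  boxes <- boxes[seq(1, nrow(boxes), by = everyK), , drop = FALSE]
  rownames(boxes) <- NULL
  masks <- lapply(seq_len(nrow(boxes)), function(q) {
    with(boxes[q, ], (lab[r0:r1, c0:c1] == label) * 1)
  })
  boxes$section <- seq_len(nrow(boxes))
  new("SectionDetection", boxes = boxes, masks = masks,
      montageDim = dim(montage), params = params)
}

#' Export detected sections as individual TIFF files
#'
#' Crops each detected section from the montage and writes it as an
#' uncompressed grayscale TIFF named by its section number.
#'
#' @param detection a [SectionDetection-class].
#' @param montage the montage the detection was run on.
#' @param dir output directory (created if missing).
#' @param applyMask zero out pixels outside the section mask.
#' @return invisibly, the vector of written file paths.
#' @export
writeSections <- function(detection, montage, dir, applyMask = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  boxes <- detection@boxes
  rng <- range(montage)
  norm <- if (diff(rng) > 0) function(m) (m - rng[1]) / diff(rng) else
    function(m) m * 0
  paths <- character(nrow(boxes))
  for (q in seq_len(nrow(boxes))) {
    crop <- montage[boxes$r0[q]:boxes$r1[q], boxes$c0[q]:boxes$c1[q]]
    if (applyMask) crop <- crop * detection@masks[[q]]
    paths[q] <- file.path(dir, sprintf("section_%03d.tif", boxes$section[q]))
    tiff::writeTIFF(norm(crop), paths[q], bits.per.sample = 16,
                    compression = "none")
  }
  invisible(paths)
}

## --- rigid alignment --------------------------------------------------------

## Bilinear rigid resampling of `img` under the transform that maps moving
## coordinates to fixed coordinates: p_fixed = R(angle)(p - c) + c + (dx, dy).
## The output lives in the fixed frame; pixels mapping outside `img` get
## `fill` (NA allowed).
.resampleRigid <- function(img, angle, dx, dy, fill = 0) {
  d <- dim(img)
  th <- -angle * pi / 180  # inverse rotation
  ctr <- (d + 1) / 2
  gr <- rep(seq_len(d[1]), d[2]) - ctr[1] - dx
  gc <- rep(seq_len(d[2]), each = d[1]) - ctr[2] - dy
  sr <- cos(th) * gr - sin(th) * gc + ctr[1]
  sc <- sin(th) * gr + cos(th) * gc + ctr[2]
  i0 <- floor(sr); j0 <- floor(sc)
  fi <- sr - i0; fj <- sc - j0
  val <- numeric(length(sr)); val[] <- NA_real_
  ok <- i0 >= 1 & j0 >= 1 & i0 < d[1] & j0 < d[2]
  if (any(ok)) {
    idx <- function(i, j) (j - 1) * d[1] + i
    v00 <- img[idx(i0[ok], j0[ok])]
    v10 <- img[idx(i0[ok] + 1, j0[ok])]
    v01 <- img[idx(i0[ok], j0[ok] + 1)]
    v11 <- img[idx(i0[ok] + 1, j0[ok] + 1)]
    val[ok] <- v00 * (1 - fi[ok]) * (1 - fj[ok]) + v10 * fi[ok] * (1 - fj[ok]) +
      v01 * (1 - fi[ok]) * fj[ok] + v11 * fi[ok] * fj[ok]
  }
  if (!is.na(fill)) val[is.na(val)] <- fill
  matrix(val, d[1], d[2])
}

## Mutual information with linear (partial-volume style) bin spreading.
.mutualInfo <- function(fixed, moved, bins = 50) {
  ok <- !is.na(moved)
  f <- fixed[ok]; m <- moved[ok]
  rf <- range(f); rm <- range(m)
  if (diff(rf) <= 0 || diff(rm) <= 0) return(0)
  bf <- (f - rf[1]) / diff(rf) * (bins - 1) + 1
  bm <- (m - rm[1]) / diff(rm) * (bins - 1) + 1
  i0 <- pmin(floor(bf), bins - 1); wi <- bf - i0
  j0 <- pmin(floor(bm), bins - 1); wj <- bm - j0
  h <- numeric(bins * bins)
  acc <- function(ii, jj, w) {
    flat <- ii + (jj - 1) * bins
    s <- rowsum(w, flat)
    h[as.integer(rownames(s))] <<- h[as.integer(rownames(s))] + s[, 1]
  }
  acc(i0, j0, (1 - wi) * (1 - wj))
  acc(i0 + 1, j0, wi * (1 - wj))
  acc(i0, j0 + 1, (1 - wi) * wj)
  acc(i0 + 1, j0 + 1, wi * wj)
  p <- h / sum(h)
  pm <- matrix(p, bins, bins)
  px <- rowSums(pm); py <- colSums(pm)
  nz <- pm > 0
  sum(pm[nz] * log(pm[nz] / outer(px, py)[nz]))
}

## integer-pixel translation maximising circular cross-correlation
.ccShift <- function(fixed, moving) {
  f <- fixed - mean(fixed)
  m <- moving - mean(moving)
  C <- Re(stats::fft(stats::fft(f) * Conj(stats::fft(m)), inverse = TRUE))
  pk <- which(C == max(C), arr.ind = TRUE)[1, ]
  d <- dim(fixed)
  sh <- pk - 1
  sh <- ifelse(sh > d / 2, sh - d, sh)
  list(shift = sh, score = max(C) /
         (sqrt(sum(f^2) * sum(m^2)) + .Machine$double.eps))
}

## register `moving` onto `fixed`: rough exhaustive angle search with FFT
## translation, then Nelder-Mead refinement of (angle, dx, dy) against
## mutual information.
.registerPair <- function(fixed, moving, downscale = 4, angleRange = 6,
                          angleStep = 1, bins = 50, maxit = 300,
                          refine = TRUE) {
  ds <- function(img) {
    if (downscale <= 1) return(img)
    EBImage::resize(img, w = max(8, round(nrow(img) / downscale)),
                    antialias = TRUE)
  }
  f4 <- ds(fixed); m4 <- ds(moving)
  best <- NULL
  for (a in seq(-angleRange, angleRange, by = angleStep)) {
    ma <- .resampleRigid(m4, a, 0, 0, fill = stats::median(m4))
    cc <- .ccShift(f4, ma)
    if (is.null(best) || cc$score > best$score)
      best <- list(angle = a, shift = cc$shift, score = cc$score)
  }
  obj4 <- function(par) {
    mm <- .resampleRigid(m4, par[1], par[2], par[3], fill = NA)
    if (mean(is.na(mm)) > 0.8) return(0)
    -.mutualInfo(f4, mm, bins)
  }
  p0 <- c(best$angle, best$shift[1], best$shift[2])
  opt <- stats::optim(p0, obj4, method = "Nelder-Mead",
                      control = list(maxit = maxit,
                                     parscale = c(0.5, 1, 1)))
  ## Nelder-Mead hitting maxit still yields a usable optimum; failure means
  ## a non-finite objective or no improvement over the rough stage
  converged <- is.finite(opt$value) && opt$value <= obj4(p0) + 1e-9
  par <- c(opt$par[1], opt$par[2] * downscale, opt$par[3] * downscale)
  if (refine && downscale > 1) {
    objF <- function(p) {
      mm <- .resampleRigid(moving, p[1], p[2], p[3], fill = NA)
      if (mean(is.na(mm)) > 0.8) return(0)
      -.mutualInfo(fixed, mm, bins)
    }
    optF <- stats::optim(par, objF, method = "Nelder-Mead",
                         control = list(maxit = maxit,
                                        parscale = c(0.2, 0.5, 0.5)))
    if (optF$value <= objF(par)) par <- optF$par
  }
  RigidTransform2D(angle = par[1], dx = par[2], dy = par[3],
                   converged = converged)
}

.composeRigid <- function(t1, t2) {
  ## apply t2 first, then t1 (both about the image centre)
  a1 <- t1@angle * pi / 180
  R <- matrix(c(cos(a1), sin(a1), -sin(a1), cos(a1)), 2)
  tt <- R %*% c(t2@dx, t2@dy) + c(t1@dx, t1@dy)
  RigidTransform2D(angle = t1@angle + t2@angle, dx = tt[1], dy = tt[2],
                   converged = t1@converged && t2@converged)
}

#' Sequentially align a stack of section images
#'
#' Registers every consecutive pair rigidly (rough exhaustive-angle search
#' with FFT cross-correlation, then Nelder-Mead refinement against a 50-bin
#' mutual-information objective, computed on images downscaled by
#' `downscale`; an optional full-resolution refinement recovers sub-pixel
#' accuracy).  Pairwise transforms are composed so every image maps into
#' the first image's frame, and the stack is resampled there.
#'
#' @param images list of equally sized 2D matrices, or a 3D array.
#' @param downscale downscaling factor for registration (4 is the
#'   conventional speed/accuracy compromise for slide scans).
#' @param angleRange,angleStep rough-search angle grid (degrees).
#' @param bins mutual-information histogram bins.
#' @param maxit optimizer iteration cap.
#' @param refine run a final full-resolution refinement.
#' @param spacing voxel spacing recorded on the output stack.
#' @return list with `transforms` (one [RigidTransform2D-class] per image,
#'   the first the identity) and `aligned` (an [ImageStack-class]).
#' @export
alignStack <- function(images, downscale = 4, angleRange = 6, angleStep = 1,
                       bins = 50, maxit = 300, refine = TRUE,
                       spacing = c(1, 1, 1)) {
  if (is.array(images) && length(dim(images)) == 3)
    images <- lapply(seq_len(dim(images)[3]), function(k) images[, , k])
  if (length(images) < 2) stop("need at least 2 images")
  d <- dim(images[[1]])
  if (!all(vapply(images, function(m) identical(dim(m), d), logical(1))))
    stop("all images must share the same shape")
  n <- length(images)
  transforms <- vector("list", n)
  transforms[[1]] <- RigidTransform2D()
  for (q in 2:n) {
    tp <- .registerPair(images[[q - 1]], images[[q]], downscale, angleRange,
                        angleStep, bins, maxit, refine)
    if (!tp@converged) {
      warning("registration of image ", q, " did not converge; identity used")
      tp <- RigidTransform2D(converged = FALSE)
    }
    transforms[[q]] <- .composeRigid(transforms[[q - 1]], tp)
  }
  fillv <- stats::median(unlist(lapply(images, stats::median)))
  aligned <- array(0, c(d, n))
  for (q in seq_len(n)) {
    tq <- transforms[[q]]
    aligned[, , q] <- .resampleRigid(images[[q]], tq@angle, tq@dx, tq@dy,
                                     fill = fillv)
  }
  list(transforms = transforms,
       aligned = ImageStack(aligned, spacing))
}
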