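## 3D reconstruction: connected-component labelling with artifact filters,
## and per-cell morphometry (volume, surface area, sphericity, Feret
## diameters, orientation, per-section profiles).

#' Label a binary mask stack and filter artifacts
#'
#' 3D connected components (26-connectivity by default), removal of
#' components smaller than `minVoxels` voxels, optional removal of
#' components spanning fewer than `minConsecutiveSections` sections
#' (validation mode uses 4, i.e. objects at least ~3 um tall), and marking
#' (not deletion) of components whose centroid section falls within the
#' first or last `dropEdgeSections` sections.
#'
#' @param mask a [MaskStack-class] (or binary 3D array plus `spacing`).
#' @param minVoxels minimum component size in voxels.
#' @param minConsecutiveSections minimum z-span in sections; NULL disables.
#' @param dropEdgeSections edge margin (sections) for centroid flagging.
#' @param connectivity 6 or 26.
#' @param spacing voxel spacing when `mask` is a plain array.
#' @return a [LabelVolume-class] with contiguous labels and `edgeLabels`.
#' @export
labelAndFilter <- function(mask, minVoxels = 8,
                           minConsecutiveSections = NULL,
                           dropEdgeSections = 3, connectivity = 26,
                           spacing = NULL) {
  if (is(mask, "MaskStack")) {
    arr <- stackData(mask); sp <- voxelSpacing(mask); org <- stackOrigin(mask)
  } else {
    arr <- mask
    sp <- spacing %||% c(1, 1, 1)
    org <- c(0, 0, 0)
  }
  if (any(arr != 0 & arr != 1)) stop("non-binary input: mask must contain only 0/1")
  dims <- dim(arr)
  lab <- label3dCpp(as.integer(arr), as.integer(dims), as.integer(connectivity))
  nlab <- max(lab)
  if (nlab == 0) {
    return(LabelVolume(array(0L, dims), sp, origin = org))
  }
  fg <- which(lab > 0L)
  lv <- lab[fg]
  k <- ((fg - 1L) %/% (dims[1] * dims[2])) + 1L
  sizes <- tabulate(lv, nlab)
  zmin <- rep(Inf, nlab); zmax <- rep(-Inf, nlab); zsum <- numeric(nlab)
  o <- order(lv)
  lvo <- lv[o]; ko <- k[o]
  brk <- c(which(diff(lvo) > 0), length(lvo))
  start <- c(1L, head(brk, -1) + 1L)
  ids <- lvo[start]
  zmin[ids] <- vapply(seq_along(ids), function(s) min(ko[start[s]:brk[s]]), numeric(1))
  zmax[ids] <- vapply(seq_along(ids), function(s) max(ko[start[s]:brk[s]]), numeric(1))
  zsum[ids] <- vapply(seq_along(ids), function(s) sum(ko[start[s]:brk[s]]), numeric(1))
  keep <- sizes >= minVoxels
  if (!is.null(minConsecutiveSections))
    keep <- keep & (zmax - zmin + 1) >= minConsecutiveSections
  remap <- integer(nlab)
  remap[keep] <- seq_len(sum(keep))
  lab2 <- array(0L, dims)
  lab2[fg] <- remap[lv]
  czSection <- round(zsum / pmax(sizes, 1))
  edge <- which(keep & (czSection <= dropEdgeSections |
                        czSection > dims[3] - dropEdgeSections))
  LabelVolume(lab2, sp, origin = org, edgeLabels = remap[edge])
}

#' Orientation vector and angle from maximum-Feret endpoints
#'
#' The orientation vector is u = (d - c) / ||d - c||; the orientation angle
#' is the angle between u and the axis `u0` (default the x-axis, pointing
#' toward the pial surface), folded to [0, 90] degrees because the Feret
#' axis has no preferred sign.
#'
#' @param cpt,dpt endpoints of the maximum Feret diameter (um).
#' @param u0 reference axis.
#' @return list with `u` (unit vector) and `theta` (degrees in [0, 90]).
#' @export
feretOrientation <- function(cpt, dpt, u0 = c(1, 0, 0)) {
  h <- dpt - cpt
  nh <- sqrt(sum(h^2))
  if (nh == 0) stop("degenerate Feret axis: endpoints coincide")
  u <- h / nh
  ct <- abs(sum(u0 * u)) / sqrt(sum(u0^2))
  list(u = u, theta = acos(pmin(1, ct)) * 180 / pi)
}

## Extract the boundary polygon (pixel centres, um) of the largest 2D
## component of a binary slice.  Returns NULL for degenerate profiles.
.sliceContour <- function(sl, sp, org) {
  labs <- EBImage::bwlabel(sl)
  if (max(labs) == 0) return(NULL)
  if (max(labs) > 1) {
    big <- which.max(tabulate(labs[labs > 0]))
    labs <- (labs == big) * 1
  }
  oc <- EBImage::ocontour(labs)
  if (!length(oc)) return(NULL)
  v <- oc[[1]] + 1  # 0-based pixel indices -> 1-based
  cbind(x = org[1] + (v[, 1] - 0.5) * sp[1],
        y = org[2] + (v[, 2] - 0.5) * sp[2])
}

#' Measure 3D cell objects from a labelled volume
#'
#' Per label: volume (voxel count times voxel volume), centroid (um),
#' surface area from a marching-tetrahedra isosurface of the Gaussian
#' pre-smoothed binary field (physically scaled for anisotropic voxels),
#' sphericity pi^(1/3) (6V)^(2/3) / A, maximum 3D Feret diameter with its
#' endpoints (maximum pairwise distance over boundary-voxel centres),
#' orientation vector / folded angle versus the x-axis, and per-section
#' profiles with area, centroid, boundary polygon and 2D maximum Feret
#' diameter.
#'
#' @param labels a [LabelVolume-class].
#' @param computeProfiles also extract per-section profiles (needed for the
#'   nucleator); disable for speed when only 3D measures are required.
#' @param smoothSigmaVox Gaussian pre-smoothing sigma in voxels for the
#'   isosurface (the default 1 balances staircase inflation against corner
#'   rounding; see the package vignette).
#' @return list with `cells` (data.frame, one row per label) and `profiles`
#'   (data.frame with a `polygon` list-column, or NULL).
#' @export
measureCells <- function(labels, computeProfiles = TRUE, smoothSigmaVox = 1) {
  arr <- stackData(labels)
  sp <- voxelSpacing(labels)
  org <- stackOrigin(labels)
  dims <- dim(arr)
  nlab <- max(arr)
  empty <- data.frame(id = integer())
  if (nlab == 0) return(list(cells = empty, profiles = NULL))
  voxvol <- prod(sp)
  fg <- which(arr > 0L)
  lv <- arr[fg]
  i <- ((fg - 1L) %% dims[1]) + 1L
  j <- (((fg - 1L) %/% dims[1]) %% dims[2]) + 1L
  k <- ((fg - 1L) %/% (dims[1] * dims[2])) + 1L
  bylab <- split(seq_along(fg), lv)
  pad <- max(4L, ceiling(3 * smoothSigmaVox) + 1L)
  rows <- vector("list", nlab)
  profs <- vector("list", nlab)
  for (L in seq_len(nlab)) {
    sel <- bylab[[as.character(L)]]
    ii <- i[sel]; jj <- j[sel]; kk <- k[sel]
    n <- length(sel)
    vol <- n * voxvol
    cx <- org[1] + (mean(ii) - 0.5) * sp[1]
    cy <- org[2] + (mean(jj) - 0.5) * sp[2]
    cz <- org[3] + (mean(kk) - 0.5) * sp[3]
    r0 <- c(min(ii), min(jj), min(kk)); r1 <- c(max(ii), max(jj), max(kk))
    cd <- r1 - r0 + 1L + 2L * pad
    bin <- array(0, cd)
    bin[cbind(ii - r0[1] + 1L + pad, jj - r0[2] + 1L + pad,
              kk - r0[3] + 1L + pad)] <- 1
    f <- if (smoothSigmaVox > 0) .gaussianSmooth(bin, smoothSigmaVox) else bin
    A <- mtAreaCpp(as.numeric(f), dim(f), 0.5, sp)
    meshFallback <- FALSE
    if (!is.finite(A) || A <= 0) {
      A <- pi^(1 / 3) * (6 * vol)^(2 / 3)
      meshFallback <- TRUE
    }
    psi <- pi^(1 / 3) * (6 * vol)^(2 / 3) / A
    ## boundary voxels: any 6-neighbour outside the object
    bnd <- .boundaryVoxels(bin, pad)
    bpts <- cbind(org[1] + (bnd[, 1] + r0[1] - pad - 1.5) * sp[1],
                  org[2] + (bnd[, 2] + r0[2] - pad - 1.5) * sp[2],
                  org[3] + (bnd[, 3] + r0[3] - pad - 1.5) * sp[3])
    if (nrow(bpts) >= 2) {
      mp <- maxPairDistCpp(bpts)
      feret3 <- mp[1]
      cpt <- bpts[mp[2], ]; dpt <- bpts[mp[3], ]
      ori <- feretOrientation(cpt, dpt)
    } else {
      feret3 <- max(sp)
      cpt <- dpt <- c(cx, cy, cz)
      ori <- list(u = c(1, 0, 0), theta = 0)
    }
    secs <- sort(unique(kk))
    feret2max <- 0
    if (computeProfiles) {
      plist <- vector("list", length(secs))
      for (s in seq_along(secs)) {
        zsec <- secs[s]
        selz <- sel[kk == zsec]
        sl <- matrix(0, r1[1] - r0[1] + 1L, r1[2] - r0[2] + 1L)
        sl[cbind(i[selz] - r0[1] + 1L, j[selz] - r0[2] + 1L)] <- 1
        subOrg <- c(org[1] + (r0[1] - 1) * sp[1], org[2] + (r0[2] - 1) * sp[2])
        poly <- .sliceContour(sl, sp, subOrg)
        areaPx <- length(selz) * sp[1] * sp[2]
        pcx <- org[1] + (mean(i[selz]) - 0.5) * sp[1]
        pcy <- org[2] + (mean(j[selz]) - 0.5) * sp[2]
        f2 <- if (!is.null(poly) && nrow(poly) >= 2) {
          hp <- poly[grDevices::chull(poly), , drop = FALSE]
          max(stats::dist(hp))
        } else sqrt(sp[1] * sp[2])
        feret2max <- max(feret2max, f2)
        plist[[s]] <- list(id = L, section = zsec, area = areaPx,
                           cx = pcx, cy = pcy, feret2d = f2, polygon = poly)
      }
      profs[[L]] <- plist
    } else {
      ## still provide the 2D Feret ceiling from pixel extents
      feret2max <- NA_real_
    }
    rows[[L]] <- data.frame(
      id = L, voxelCount = n, volume = vol, cx = cx, cy = cy, cz = cz,
      surface = A, sphericity = psi, feret3d = feret3,
      feretCx = cpt[1], feretCy = cpt[2], feretCz = cpt[3],
      feretDx = dpt[1], feretDy = dpt[2], feretDz = dpt[3],
      ux = ori$u[1], uy = ori$u[2], uz = ori$u[3], thetaDeg = ori$theta,
      nSections = length(secs), firstSection = min(kk), lastSection = max(kk),
      feret2dMax = feret2max,
      edgeFlag = L %in% labels@edgeLabels, meshFallback = meshFallback)
  }
  cells <- do.call(rbind, rows)
  profdf <- NULL
  if (computeProfiles) {
    flat <- unlist(profs, recursive = FALSE)
    profdf <- data.frame(
      id = vapply(flat, `[[`, integer(1), "id"),
      section = vapply(flat, `[[`, numeric(1), "section"),
      area = vapply(flat, `[[`, numeric(1), "area"),
      cx = vapply(flat, `[[`, numeric(1), "cx"),
      cy = vapply(flat, `[[`, numeric(1), "cy"),
      feret2d = vapply(flat, `[[`, numeric(1), "feret2d"))
    profdf$polygon <- lapply(flat, `[[`, "polygon")
  }
  list(cells = cells, profiles = profdf)
}

## boundary voxels of a padded binary array; returns index matrix (i, j, k)
## in the padded frame.
.boundaryVoxels <- function(bin, pad) {
  d <- dim(bin)
  inner <- bin > 0
  core <- inner
  sh <- function(a, off) {
    out <- array(FALSE, d)
    src <- list(seq_len(d[1]) - off[1], seq_len(d[2]) - off[2],
                seq_len(d[3]) - off[3])
    ok <- lapply(seq_len(3), function(m) src[[m]] >= 1 & src[[m]] <= d[m])
    out[ok[[1]], ok[[2]], ok[[3]]] <-
      a[src[[1]][ok[[1]]], src[[2]][ok[[2]]], src[[3]][ok[[3]]]]
    out
  }
  for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
    core <- core & sh(inner, off)
  }
  which(inner & !core, arr.ind = TRUE)
}
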