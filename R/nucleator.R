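## Nucleator stereology: ray lengths from a profile centroid to the
## boundary, 2D volume / diameter estimators, and the 3D sphere-equivalent
## diameter used for the 2D-versus-3D size comparison.

#' Ray lengths from a profile centroid to its boundary
#'
#' Casts `nRays` rays from the profile centroid at equal angular spacing
#' 360 / nRays degrees starting from a uniformly random (seeded) start
#' angle, and returns the distance to the first boundary intersection for
#' each ray.
#'
#' @param polygon boundary polygon, m x 2 matrix of (x, y) in um (open or
#'   closed); vertex order is irrelevant.
#' @param centroid profile centroid; NULL computes the polygon (shoelace)
#'   centroid.  Must lie strictly inside the boundary.
#' @param nRays number of rays (5 in the classical design, spacing 72
#'   degrees).
#' @param startAngle first ray angle in degrees; NULL draws it uniformly.
#' @param seed RNG seed for the random start angle.
#' @return numeric vector of `nRays` lengths (um).
#' @export
profileRayLengths <- function(polygon, centroid = NULL, nRays = 5,
                              startAngle = NULL, seed = NULL) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3) stop("degenerate profile: fewer than 3 vertices")
  if (all(polygon[1, ] == polygon[nrow(polygon), ]))
    polygon <- polygon[-nrow(polygon), , drop = FALSE]
  if (is.null(centroid))
    centroid <- .polygonAreaCentroid(polygon)$centroid
  if (!.pointsInPolygon(matrix(centroid, 1), polygon))
    stop("profile skipped: centroid lies outside the boundary polygon")
  if (is.null(startAngle))
    startAngle <- .withSeed(seed, stats::runif(1, 0, 360))
  ang <- (startAngle + (seq_len(nRays) - 1) * 360 / nRays) * pi / 180
  p1 <- polygon
  p2 <- polygon[c(seq_len(nrow(polygon))[-1], 1), , drop = FALSE]
  ex <- p2[, 1] - p1[, 1]; ey <- p2[, 2] - p1[, 2]
  rx <- p1[, 1] - centroid[1]; ry <- p1[, 2] - centroid[2]
  vapply(ang, function(a) {
    dx <- cos(a); dy <- sin(a)
    ## solve centroid + s * d = p1 + t * e, s > 0, t in [0, 1]
    den <- dx * ey - dy * ex
    ok <- abs(den) > 1e-14
    t <- (dy * rx - dx * ry)[ok] / den[ok]
    s <- (rx * ey - ry * ex)[ok] / den[ok]
    hit <- t >= -1e-12 & t <= 1 + 1e-12 & s > 1e-12
    if (!any(hit)) return(NA_real_)
    min(s[hit])
  }, numeric(1))
}

#' Nucleator size estimates for a reconstructed cell
#'
#' Variant `largest` applies the ray probe to the largest-area profile of
#' the cell; variant `all` applies it to every profile and averages all ray
#' lengths.  The mean segment length l is plugged into
#' Volume = (4/3) pi l^3 and Diameter = 2 l — the cube of the mean, as in
#' the tabulated workflow this package mirrors.  `classical = TRUE` instead
#' uses the unbiased classical nucleator form (4/3) pi mean(l^3).
#'
#' @param profiles profile table for one cell ([measureCells()] output
#'   filtered to a single id), with `area` and `polygon` columns.
#' @param variant "largest" or "all".
#' @param nRays rays per profile.
#' @param seed RNG seed for the random start angles.
#' @param classical use mean of cubed lengths instead of cubed mean.
#' @return list: meanRayLength (um), volume (um^3), diameter (um), variant,
#'   nProfiles, lengths.
#' @export
nucleatorEstimates <- function(profiles, variant = c("largest", "all"),
                               nRays = 5, seed = NULL, classical = FALSE) {
  variant <- match.arg(variant)
  ok <- !vapply(profiles$polygon, is.null, logical(1)) &
    vapply(profiles$polygon, function(p) !is.null(p) && nrow(p) >= 3, logical(1))
  profiles <- profiles[ok, , drop = FALSE]
  if (nrow(profiles) == 0) stop("no valid profiles for this cell")
  use <- if (variant == "largest") which.max(profiles$area) else seq_len(nrow(profiles))
  lens <- numeric(0)
  for (q in seq_along(use)) {
    p <- use[q]
    li <- tryCatch(
      profileRayLengths(profiles$polygon[[p]], nRays = nRays,
                        seed = if (is.null(seed)) NULL else .childSeed(seed, p)),
      error = function(e) NULL)
    if (!is.null(li)) lens <- c(lens, li[is.finite(li)])
  }
  if (!length(lens)) stop("no valid profiles for this cell")
  lbar <- mean(lens)
  vol <- if (classical) 4 / 3 * pi * mean(lens^3) else 4 / 3 * pi * lbar^3
  list(meanRayLength = lbar, volume = vol, diameter = 2 * lbar,
       variant = variant, nProfiles = length(use), lengths = lens)
}

#' Nucleator estimates for every cell of a measurement set
#'
#' @param measurements output of [measureCells()] (with profiles).
#' @param nRays rays per profile.
#' @param seed RNG seed.
#' @param classical see [nucleatorEstimates()].
#' @return the cell table with appended columns volL, diaL, volAll, diaAll,
#'   dia3d.
#' @export
nucleatorTable <- function(measurements, nRays = 5, seed = NULL,
                           classical = FALSE) {
  cells <- measurements$cells
  profs <- measurements$profiles
  if (is.null(profs)) stop("measurements carry no profiles; rerun measureCells(computeProfiles = TRUE)")
  cells$volL <- cells$diaL <- cells$volAll <- cells$diaAll <- NA_real_
  for (r in seq_len(nrow(cells))) {
    pr <- profs[profs$id == cells$id[r], , drop = FALSE]
    sd1 <- if (is.null(seed)) NULL else .childSeed(seed, 2 * r)
    sd2 <- if (is.null(seed)) NULL else .childSeed(seed, 2 * r + 1)
    eL <- tryCatch(nucleatorEstimates(pr, "largest", nRays, sd1, classical),
                   error = function(e) NULL)
    eA <- tryCatch(nucleatorEstimates(pr, "all", nRays, sd2, classical),
                   error = function(e) NULL)
    if (!is.null(eL)) { cells$volL[r] <- eL$volume; cells$diaL[r] <- eL$diameter }
    if (!is.null(eA)) { cells$volAll[r] <- eA$volume; cells$diaAll[r] <- eA$diameter }
  }
  cells$dia3d <- sphereEquivalentDiameter(cells$volume)
  cells
}

#' Sphere-equivalent diameter of a volume
#'
#' d = (6 V / pi)^(1/3): the diameter of the sphere with the same volume,
#' the 3D reference in the 2D-versus-3D size comparison.
#'
#' @param volume volume(s) in um^3; must be positive.
#' @return diameter(s) in um.
#' @export
sphereEquivalentDiameter <- function(volume) {
  if (any(volume <= 0)) stop("volume must be positive")
  (6 * volume / pi)^(1 / 3)
}
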