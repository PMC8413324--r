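## Cylindrical K-function with translation edge correction and
## extreme-rank-length (ERL) global envelope tests against CSR.

#' Cylindrical K-function of a 3D point pattern
#'
#' Estimates K_u(r, t) on a full (r, t) grid: for each ordered pair the
#' displacement h is tested against the cylinder of radius r and half-height
#' t aligned with u (|h . u| <= t and the perpendicular component <= r),
#' with translation edge correction 1 / |W intersect W_h| (a product of 1D
#' overlaps for a box window) and the unbiased-under-CSR intensity-square
#' estimator n (n - 1) / |W|^2.  Under CSR, E K_u(r, t) = 2 pi r^2 t.
#'
#' @param pattern a [PointPattern3D-class] with at least 2 points.
#' @param direction cylinder axis: "x", "y", "z" or a 3-vector (normalised
#'   internally).
#' @param r radii grid (um, non-negative, increasing).
#' @param t half-height grid (um, non-negative, increasing).
#' @return a [CylKEstimate-class].
#' @export
cylindricalK <- function(pattern, direction = "x",
                         r = seq(0, 25, length.out = 64),
                         t = seq(0, 80, length.out = 64)) {
  n <- npoints(pattern)
  if (n < 2) stop("cylindrical K requires at least 2 points")
  if (any(r < 0) || any(t < 0)) stop("r and t must be non-negative")
  if (is.unsorted(r) || is.unsorted(t)) stop("r and t must be increasing")
  u <- .parseDirection(direction)
  w <- patternWindow(pattern)
  K <- cylKCpp(patternCoords(pattern), u, as.numeric(r), as.numeric(t),
               w[1, ], w[2, ])
  new("CylKEstimate", direction = u, r = as.numeric(r), t = as.numeric(t),
      K = K, n = as.integer(n), window = w)
}

.parseDirection <- function(direction) {
  if (is.character(direction)) {
    u <- switch(direction,
                x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1),
                stop("unknown direction label: ", direction))
  } else {
    u <- as.numeric(direction)
    nu <- sqrt(sum(u^2))
    if (nu == 0) stop("direction must be a nonzero vector")
    u <- u / nu
  }
  u
}

#' Theoretical cylindrical K under complete spatial randomness
#'
#' @param r,t grids (um).
#' @return matrix 2 pi r^2 t over the grid.
#' @export
csrTheoreticalK <- function(r, t) {
  outer(2 * pi * r^2, t)
}

#' Centered cylindrical K values (K minus the CSR expectation)
#'
#' @param estimate a [CylKEstimate-class].
#' @return matrix of K - 2 pi r^2 t.
#' @export
centeredK <- function(estimate) {
  estimate@K - csrTheoreticalK(estimate@r, estimate@t)
}

## --- extreme rank length ordering ------------------------------------------

## Pointwise two-sided ranks: for each grid cell, the depth of each curve
## from the most extreme value on either side (1 = most extreme).  Ties get
## the most extreme (minimum) depth.
.pointwiseRanks <- function(curves) {
  s <- nrow(curves)
  up <- apply(curves, 2, rank, ties.method = "min")
  dn <- apply(-curves, 2, rank, ties.method = "min")
  pmin(up, dn)
}

## ERL ordering: curve A is more extreme than B when its vector of sorted
## pointwise ranks is lexicographically smaller; equivalently when its
## count vector (how many cells attain depth 1, 2, ...) is lexicographically
## larger.  Returns increasing extremeness ranks (1 = most extreme) with
## ties sharing the minimum rank.
.erlOrder <- function(ranks) {
  s <- nrow(ranks)
  maxDepth <- max(ranks)
  cnt <- t(apply(ranks, 1, tabulate, nbins = maxDepth))
  ord <- do.call(order, c(lapply(seq_len(ncol(cnt)), function(j) -cnt[, j])))
  ## assign ranks, sharing ranks on exact count-vector ties
  erl <- integer(s)
  rnk <- 1L
  for (q in seq_len(s)) {
    if (q > 1 && !identical(cnt[ord[q], ], cnt[ord[q - 1], ])) rnk <- q
    erl[ord[q]] <- rnk
  }
  erl
}

#' ERL global envelope test of CSR for the cylindrical K-function
#'
#' Simulates `nsim` CSR patterns (binomial by default: the observed number
#' of points, uniformly in the observed window), computes the cylindrical K
#' for the observed and simulated patterns on the same grid, ranks the
#' curves by extreme rank length (two-sided), and builds the `level` global
#' envelope as the pointwise hull of the curves remaining after discarding
#' the floor((1 - level) (nsim + 1)) most extreme ones.  The Monte-Carlo
#' p-value is the (tie-averaged conservative) proportion of curves at least
#' as extreme as the observed one.  Cells of the grid where the observed
#' curve exits the envelope are flagged "above" (cylindrical clustering in
#' direction u) or "below" (repulsion).
#'
#' @param pattern observed [PointPattern3D-class].
#' @param direction cylinder axis (see [cylindricalK()]); may be a list /
#'   character vector of several directions, in which case the same null
#'   simulations are reused and one envelope per direction is returned.
#' @param r,t evaluation grids (um); the varying-(r, t) design uses a
#'   64 x 64 grid over [0, 25] x [0, 80], the fixed-height design a single
#'   t = 80.
#' @param nsim number of CSR simulations (>= 99; 2000 and 4000 match the
#'   published designs for the fixed-height and grid modes).
#' @param level envelope level.
#' @param seed integer seed.
#' @param csr "binomial" (condition on n) or "poisson".
#' @return a [GlobalEnvelope-class], or a named list of them for several
#'   directions.
#' @export
globalEnvelopeTest <- function(pattern, direction = "x",
                               r = seq(0, 25, length.out = 64),
                               t = seq(0, 80, length.out = 64),
                               nsim = 199, level = 0.95, seed = NULL,
                               csr = c("binomial", "poisson")) {
  csr <- match.arg(csr)
  if (nsim < 99) stop("nsim must be at least 99")
  if (!length(r) || !length(t)) stop("empty evaluation grid")
  n <- npoints(pattern)
  w <- patternWindow(pattern)
  dirs <- if (is.list(direction)) direction else
    if (is.character(direction) && length(direction) > 1) as.list(direction) else
      list(direction)
  sims <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    sd <- if (is.null(seed)) NULL else .childSeed(seed, s)
    sims[[s]] <- if (csr == "binomial") {
      simulateCSRPattern(n = n, windowBox = w, seed = sd)
    } else {
      simulateCSRPattern(intensity = patternIntensity(pattern), windowBox = w,
                         seed = sd)
    }
  }
  res <- lapply(dirs, function(d) {
    obs <- cylindricalK(pattern, d, r, t)
    curves <- matrix(0, nsim + 1, length(r) * length(t))
    curves[1, ] <- as.vector(obs@K)
    for (s in seq_len(nsim))
      curves[s + 1, ] <- as.vector(cylindricalK(sims[[s]], d, r, t)@K)
    ranks <- .pointwiseRanks(curves)
    erl <- .erlOrder(ranks)
    nAsExtreme <- sum(erl <= erl[1])
    nMoreExtreme <- sum(erl < erl[1])
    p <- nAsExtreme / (nsim + 1)
    pInt <- c((nMoreExtreme + 1) / (nsim + 1), nAsExtreme / (nsim + 1))
    kOut <- floor((1 - level) * (nsim + 1))
    keep <- erl > .kthExtreme(erl, kOut)
    if (!any(keep)) keep <- rep(TRUE, nsim + 1)
    lower <- matrix(apply(curves[keep, , drop = FALSE], 2, min),
                    length(r), length(t))
    upper <- matrix(apply(curves[keep, , drop = FALSE], 2, max),
                    length(r), length(t))
    decision <- matrix("inside", length(r), length(t))
    decision[obs@K > upper] <- "above"
    decision[obs@K < lower] <- "below"
    new("GlobalEnvelope", estimate = obs, lower = lower, upper = upper,
        nsim = as.integer(nsim), level = level, pValue = p,
        pInterval = pInt, erlRank = as.numeric(erl[1]), decision = decision)
  })
  if (length(res) == 1) res[[1]] else {
    names(res) <- vapply(dirs, function(d)
      if (is.character(d)) d else paste(signif(d, 3), collapse = ","),
      character(1))
    res
  }
}

## threshold ERL rank such that curves with rank <= threshold are the
## kOut most extreme (ties counted together; conservative: discard fewer
## when a tie straddles the cut).
.kthExtreme <- function(erl, kOut) {
  if (kOut <= 0) return(0L)
  se <- sort(erl)
  cut <- se[kOut]
  if (sum(erl <= cut) > kOut) {
    cand <- se[se < cut]
    if (!length(cand)) return(0L)
    cut <- max(cand)
  }
  cut
}

#' Marginal projection densities of a 3D pattern (homogeneity diagnostic)
#'
#' Kernel-smoothed densities of the coordinate projections onto each axis,
#' for eyeballing homogeneity before a cylindrical K analysis.
#'
#' @param pattern a [PointPattern3D-class].
#' @param bw bandwidth in um.
#' @return named list of [stats::density()] objects (x, y, z).
#' @export
projectionDensities <- function(pattern, bw = 10) {
  xyz <- patternCoords(pattern)
  list(x = stats::density(xyz[, 1], bw = bw),
       y = stats::density(xyz[, 2], bw = bw),
       z = stats::density(xyz[, 3], bw = bw))
}
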