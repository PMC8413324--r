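## Layer III localisation, pyramidal / non-pyramidal classification with a
## two-component Gaussian mixture over (volume, sphericity), log-Feret
## outlier removal, and number density.

#' Locate the layer III analysis window from centroid density
#'
#' Auto mode builds a kernel-smoothed density of centroid x-coordinates
#' (x points toward the pial surface), finds the two dominant local maxima
#' (the dense layer II and layer IV bands), and returns the open interval
#' between the peaks shrunk by `margin` times the inter-peak distance on
#' each side.  Manual mode passes user bounds through (the click-based ROI
#' of the original workflow).
#'
#' @param x numeric vector of centroid x-coordinates (um), or a cell table
#'   with a `cx` column.
#' @param mode "auto" or "manual".
#' @param manualBounds (lo, hi) for manual mode, and the fallback when auto
#'   mode cannot resolve two peaks.
#' @param margin fraction of the inter-peak distance trimmed from each side.
#' @param bw kernel bandwidth in um for the density estimate.
#' @return a [LayerWindow-class].
#' @export
selectLayer3 <- function(x, mode = c("auto", "manual"), manualBounds = NULL,
                         margin = 0.1, bw = 15) {
  mode <- match.arg(mode)
  if (is.data.frame(x)) x <- x$cx
  if (mode == "manual") {
    if (is.null(manualBounds)) stop("manual mode requires 'manualBounds'")
    return(new("LayerWindow", bounds = as.numeric(manualBounds),
               mode = "manual", peaks = numeric()))
  }
  if (length(x) < 100)
    stop("auto mode needs at least 100 centroids")
  d <- stats::density(x, bw = bw)
  y <- d$y
  locmax <- which(diff(sign(diff(y))) == -2) + 1
  if (length(locmax) < 2) {
    if (!is.null(manualBounds)) {
      return(new("LayerWindow", bounds = as.numeric(manualBounds),
                 mode = "manual", peaks = numeric()))
    }
    stop("layers not resolvable: fewer than two density peaks; supply manual bounds")
  }
  top2 <- locmax[order(y[locmax], decreasing = TRUE)][1:2]
  peaks <- sort(d$x[top2])
  gap <- diff(peaks)
  bounds <- c(peaks[1] + margin * gap, peaks[2] - margin * gap)
  new("LayerWindow", bounds = bounds, mode = "auto", peaks = peaks)
}

## --- two-component GMM ------------------------------------------------------

.dmvnorm2 <- function(X, mu, S) {
  ## bivariate normal density, X n x 2
  dS <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
  if (dS <= 0) return(rep(NA_real_, nrow(X)))
  Si <- matrix(c(S[2, 2], -S[1, 2], -S[2, 1], S[1, 1]), 2) / dS
  d1 <- X[, 1] - mu[1]; d2 <- X[, 2] - mu[2]
  q <- Si[1, 1] * d1^2 + 2 * Si[1, 2] * d1 * d2 + Si[2, 2] * d2^2
  exp(-q / 2) / (2 * pi * sqrt(dS))
}

## EM for a 2-component full-covariance bivariate Gaussian mixture with a
## small ridge on the covariance diagonals; seeded k-means initialisation.
.fitGMM2 <- function(X, seed = NULL, reg = 1e-6, maxit = 500, tol = 1e-8) {
  n <- nrow(X)
  km <- .withSeed(seed, stats::kmeans(X, centers = 2, nstart = 10))
  z <- matrix(0, n, 2)
  z[cbind(seq_len(n), km$cluster)] <- 1
  ll0 <- -Inf
  w <- mu <- Sg <- NULL
  for (it in seq_len(maxit)) {
    nk <- colSums(z)
    w <- nk / n
    mu <- lapply(1:2, function(g) colSums(X * z[, g]) / nk[g])
    Sg <- lapply(1:2, function(g) {
      xc <- sweep(X, 2, mu[[g]])
      S <- crossprod(xc * z[, g], xc) / nk[g]
      S + diag(reg, 2)
    })
    f1 <- w[1] * .dmvnorm2(X, mu[[1]], Sg[[1]])
    f2 <- w[2] * .dmvnorm2(X, mu[[2]], Sg[[2]])
    tot <- f1 + f2
    if (any(!is.finite(tot)) || any(tot <= 0)) break
    ll <- sum(log(tot))
    z <- cbind(f1 / tot, f2 / tot)
    if (is.finite(ll0) && abs(ll - ll0) < tol * (abs(ll0) + 1)) break
    ll0 <- ll
  }
  list(weights = w, means = mu, covariances = Sg, z = z,
       cluster = max.col(z), loglik = ll0)
}

#' Split cells into pyramidal and non-pyramidal with a 2-component GMM
#'
#' The mixture is fitted on the raw (volume um^3, sphericity) features of
#' the cells with volume below the dataset mean — pyramidal-cell top/bottom
#' profiles masquerade as small round cells only at the small end of the
#' volume scale.  The component with the lower mean volume (tie: lower mean
#' sphericity) defines the non-pyramidal class; its hard assignments are
#' labelled `non_pyramidal` and every other cell, including all above-mean
#' cells, `pyramidal`.
#'
#' @param cells cell table with `volume` and `sphericity` columns.
#' @param seed integer seed for the k-means initialisation.
#' @param reg ridge added to covariance diagonals.
#' @return list with `labels` (character vector), `gmm` (weights, means,
#'   covariances), `fitIndex` (rows used for fitting) and
#'   `excludedFraction` (fraction labelled non-pyramidal).
#' @export
gmmSplit <- function(cells, seed = NULL, reg = 1e-6) {
  stopifnot(all(c("volume", "sphericity") %in% names(cells)))
  v <- cells$volume
  fit <- which(v < mean(v))
  if (length(fit) < 20)
    stop("need at least 20 cells below the mean volume to fit the mixture")
  X <- cbind(v[fit], cells$sphericity[fit])
  if (any(apply(X, 2, stats::sd) == 0))
    stop("degenerate data: a feature has zero variance")
  g <- .fitGMM2(X, seed = seed, reg = reg)
  mv <- c(g$means[[1]][1], g$means[[2]][1])
  ms <- c(g$means[[1]][2], g$means[[2]][2])
  lowComp <- if (abs(diff(mv)) > 1e-12) which.min(mv) else which.min(ms)
  labels <- rep("pyramidal", nrow(cells))
  labels[fit[g$cluster == lowComp]] <- "non_pyramidal"
  list(labels = labels,
       gmm = list(weights = g$weights, means = g$means,
                  covariances = g$covariances, lowComponent = lowComp),
       fitIndex = fit,
       excludedFraction = mean(labels == "non_pyramidal"))
}

#' Flag oversized objects by log-Feret outlier screening
#'
#' Over the pyramidal cells, log(2D max Feret) and log(3D max Feret) are
#' each screened against mean + `nsd` standard deviations; cells exceeding
#' either bound become `outlier` (upper tail only — the screen targets
#' merged cells and vessels, which are large).
#'
#' @param cells cell table with `feret2dMax` and `feret3d` columns.
#' @param labels character vector from [gmmSplit()].
#' @param nsd SD multiplier.
#' @return updated labels with `outlier` entries.
#' @export
outlierFilter <- function(cells, labels, nsd = 3) {
  pyr <- which(labels == "pyramidal")
  if (length(pyr) < 10)
    stop("need at least 10 pyramidal cells for outlier screening")
  out <- rep(FALSE, length(pyr))
  for (col in c("feret2dMax", "feret3d")) {
    lf <- log(cells[[col]][pyr])
    s <- stats::sd(lf)
    if (is.na(s) || s == 0) next
    out <- out | lf > mean(lf) + nsd * s
  }
  labels[pyr[out]] <- "outlier"
  labels
}

#' Number density of cells in an analysis window
#'
#' @param count number of cells.
#' @param volumeMm3 window volume in mm^3.
#' @return density in mm^-3.
#' @export
numberDensity <- function(count, volumeMm3) {
  if (count < 0) stop("count must be non-negative")
  if (volumeMm3 <= 0) stop("window volume must be positive")
  count / volumeMm3
}
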