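## Internal numeric and RNG helpers shared across modules.

#' Round half away from zero
#'
#' Tabular reporting in this package rounds half-up (0.005 -> 0.01), unlike
#' [base::round()] which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`;
## the caller's RNG stream is untouched.  seed = NULL evaluates as-is.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a reproducible child seed from a base seed (kept below 2^31).
.childSeed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.double(seed) * 48271 + 7919 * k) %% 2147483587
}

## --- separable Gaussian smoothing -----------------------------------------

## 1D Gaussian convolution along rows of a matrix view, with border
## renormalisation of the truncated kernel (flat signals stay flat).
.convRows <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  n <- nrow(m)
  out <- matrix(0, n, ncol(m))
  cover <- numeric(n)
  for (o in -r:r) {
    w <- k[o + r + 1]
    src <- seq_len(n) + o
    ok <- src >= 1L & src <= n
    out[ok, ] <- out[ok, ] + w * m[src[ok], , drop = FALSE]
    cover[ok] <- cover[ok] + w
  }
  out / cover
}

.smoothAlong <- function(a, sigma, along) {
  if (sigma <= 0) return(a)
  d <- dim(a)
  if (along == 1) {
    out <- .convRows(matrix(a, d[1], d[2] * d[3]), sigma)
  } else if (along == 3) {
    out <- t(.convRows(t(matrix(a, d[1] * d[2], d[3])), sigma))
  } else {
    ap <- aperm(a, c(2, 1, 3))
    sm <- .convRows(matrix(ap, d[2], d[1] * d[3]), sigma)
    return(aperm(array(sm, c(d[2], d[1], d[3])), c(2, 1, 3)))
  }
  array(out, d)
}

## sigma: per-dimension in voxel units (recycled).  The in-plane part runs
## through EBImage::filter2 (FFT, framewise on 3D arrays, replicated
## borders) when the kernel fits; the z part and small arrays use the
## direct separable path.
.gaussianSmooth <- function(a, sigma) {
  d <- dim(a)
  sigma <- rep_len(sigma, length(d))
  if (length(d) == 3 && sigma[1] > 0 && sigma[2] > 0) {
    r1 <- max(1L, ceiling(3 * sigma[1])); r2 <- max(1L, ceiling(3 * sigma[2]))
    if (2 * r1 + 1 < d[1] && 2 * r2 + 1 < d[2]) {
      k1 <- stats::dnorm(-r1:r1, sd = sigma[1])
      k2 <- stats::dnorm(-r2:r2, sd = sigma[2])
      kern <- outer(k1 / sum(k1), k2 / sum(k2))
      a <- EBImage::filter2(a, kern, boundary = "replicate")
      return(.smoothAlong(a, sigma[3], 3))
    }
  }
  for (i in seq_along(d)) a <- .smoothAlong(a, sigma[i], i)
  a
}

.gaussianSmooth2D <- function(m, sigma) {
  a <- array(m, dim = c(dim(m), 1L))
  out <- .gaussianSmooth(a, c(rep_len(sigma, 2), 0))
  if (length(dim(out)) == 3) out <- out[, , 1]
  out
}

## --- Otsu threshold on raw values ------------------------------------------

.otsu <- function(x, nbins = 256) {
  rng <- range(x, finite = TRUE)
  if (diff(rng) <= 0) return(rng[1])
  h <- as.numeric(tabulate(pmin(nbins, 1L + floor((x - rng[1]) / diff(rng) * nbins)),
                           nbins))
  mids <- rng[1] + (seq_len(nbins) - 0.5) / nbins * diff(rng)
  w1 <- cumsum(h)
  w2 <- sum(h) - w1
  m1 <- cumsum(h * mids) / pmax(w1, 1)
  m2 <- (sum(h * mids) - cumsum(h * mids)) / pmax(w2, 1)
  between <- w1 * w2 * (m1 - m2)^2
  between[nbins] <- 0
  mids[which.max(between)]
}

## --- point-in-polygon (ray casting), vectorised over query points ----------

.pointsInPolygon <- function(pts, poly) {
  ## pts: n x 2, poly: m x 2 (open or closed)
  if (all(poly[1, ] == poly[nrow(poly), ])) poly <- poly[-nrow(poly), , drop = FALSE]
  m <- nrow(poly)
  x <- pts[, 1]; y <- pts[, 2]
  inside <- logical(length(x))
  j <- m
  for (i in seq_len(m)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

## Polygon area and centroid (shoelace); vertices as m x 2 matrix.
.polygonAreaCentroid <- function(poly) {
  if (all(poly[1, ] == poly[nrow(poly), ])) poly <- poly[-nrow(poly), , drop = FALSE]
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) {
    return(list(area = 0, centroid = colMeans(poly)))
  }
  cx <- sum((x + xn) * cr) / (6 * a)
  cy <- sum((y + yn) * cr) / (6 * a)
  list(area = abs(a), centroid = c(cx, cy))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
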