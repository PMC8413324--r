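# Fixtures built in code: digitised solids, textured images, tiny scenes.

# binary ball of radius r (um) digitised at spacing sp, padded border
ballVolume <- function(r = 10, sp = c(0.5, 0.5, 0.5), pad = 4) {
  ext <- r + pad * max(sp)
  nd <- ceiling(2 * ext / sp)
  ax <- lapply(1:3, function(d) (seq_len(nd[d]) - 0.5) * sp[d] - ext)
  d2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  LabelVolume((d2 <= r^2) * 1, sp)
}

# axis-aligned ellipsoid with semi-axes (a, b, c) um
ellipsoidVolume <- function(semi, sp = c(0.25, 0.25, 0.25), pad = 4) {
  ext <- semi + pad * max(sp)
  nd <- ceiling(2 * ext / sp)
  ax <- lapply(1:3, function(d) (seq_len(nd[d]) - 0.5) * sp[d] - ext[d])
  q <- outer(outer(ax[[1]]^2 / semi[1]^2, ax[[2]]^2 / semi[2]^2, "+"),
             ax[[3]]^2 / semi[3]^2, "+")
  LabelVolume((q <= 1) * 1, sp)
}

# exact voxel cube of side `side` um
cubeVolume <- function(side = 20, sp = 0.5, pad = 6) {
  n <- round(side / sp)
  N <- n + 2 * pad
  a <- array(0, c(N, N, N))
  a[(pad + 1):(pad + n), (pad + 1):(pad + n), (pad + 1):(pad + n)] <- 1
  LabelVolume(a, rep(sp, 3))
}

# smooth random texture (for registration tests)
texturedImage <- function(n = 160, seed = 1, sigma = 3) {
  withr::with_seed(seed, {
    img <- matrix(stats::rnorm(n * n), n, n)
    img <- CortexMorph:::.gaussianSmooth2D(img, sigma)
    (img - min(img)) / diff(range(img))
  })
}

# montage of textured rectangles on a flat background, with known boxes in
# reading order bottom-right to top-left (2 shelf rows x 3 columns)
montageFixture <- function(seed = 5) {
  withr::with_seed(seed, {
    m <- matrix(0.5, 260, 320)
    boxes <- list()
    k <- 0
    for (rowi in 1:2) for (coli in 1:3) {
      k <- k + 1
      r0 <- 20 + (rowi - 1) * 130
      c0 <- 15 + (coli - 1) * 105
      h <- 80; w <- 70
      m[r0:(r0 + h - 1), c0:(c0 + w - 1)] <-
        matrix(stats::runif(h * w), h, w)
      boxes[[k]] <- c(r0 = r0, r1 = r0 + h - 1, c0 = c0, c1 = c0 + w - 1)
    }
    # reading order: bottom shelf first (rowi = 2), right to left
    readingOrder <- c(6, 5, 4, 3, 2, 1)
    list(montage = m, boxes = boxes, readingOrder = readingOrder)
  })
}

# regular polygon approximating a circle (vertices in um)
circlePolygon <- function(r = 5, n = 2000, centre = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(centre[1] + r * cos(th), centre[2] + r * sin(th))
}

squarePolygon <- function(side = 4, centre = c(0, 0)) {
  h <- side / 2
  cbind(centre[1] + c(-h, h, h, -h), centre[2] + c(-h, -h, h, h))
}

# small synthetic scene for fast pipeline checks: the window is tiny, so a
# guaranteed column count is set explicitly instead of the density-derived
# default (which would round to zero columns)
smallSceneParams <- function(seed = 7, ...) {
  sceneParams(windowBox = c(80, 80, 50), columnIntensity = 8e-4,
              pointsPerColumnMean = 8, seed = seed, ...)
}
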