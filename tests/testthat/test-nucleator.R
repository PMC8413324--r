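test_that("rays on a circle all equal the radius, for any start angle", {
  poly <- circlePolygon(r = 5)
  for (a0 in c(0, 13.7, 72, 211)) {
    lens <- profileRayLengths(poly, nRays = 5, startAngle = a0)
    expect_equal(lens, rep(5, 5), tolerance = 1e-3)
  }
})

test_that("rays on a square match the closed form 2 / max(|cos|, |sin|)", {
  poly <- squarePolygon(side = 4)
  lens <- profileRayLengths(poly, nRays = 5, startAngle = 0)
  ang <- (0 + (0:4) * 72) * pi / 180
  closed <- 2 / pmax(abs(cos(ang)), abs(sin(ang)))
  expect_equal(lens, closed, tolerance = 1e-9)
  expect_equal(lens, c(2, 2.1029, 2.4721, 2.4721, 2.1029), tolerance = 1e-4)
  expect_equal(mean(lens), 2.230, tolerance = 1e-3)
})

test_that("ray lengths agree with dense boundary sampling on convex profiles", {
  withr::with_seed(20, {
    for (q in 1:5) {
      # random convex polygon via convex hull of points on an ellipse + jitter
      th <- sort(runif(40, 0, 2 * pi))
      pts <- cbind((3 + runif(40)) * cos(th), (2 + runif(40)) * sin(th))
      hull <- pts[grDevices::chull(pts), ]
      a0 <- runif(1, 0, 360)
      lens <- profileRayLengths(hull, nRays = 7, startAngle = a0)
      # oracle: dense sampling of the boundary, nearest-angle lookup
      dense <- do.call(rbind, lapply(seq_len(nrow(hull)), function(e) {
        p1 <- hull[e, ]; p2 <- hull[if (e == nrow(hull)) 1 else e + 1, ]
        s <- seq(0, 1, length.out = 20000)
        cbind(p1[1] + s * (p2[1] - p1[1]), p1[2] + s * (p2[2] - p1[2]))
      }))
      ctr <- CortexMorph:::.polygonAreaCentroid(hull)$centroid
      bth <- atan2(dense[, 2] - ctr[2], dense[, 1] - ctr[1])
      bd <- sqrt((dense[, 1] - ctr[1])^2 + (dense[, 2] - ctr[2])^2)
      for (k in 1:7) {
        alpha <- (a0 + (k - 1) * 360 / 7) * pi / 180
        dang <- abs(((bth - alpha + pi) %% (2 * pi)) - pi)
        expect_equal(lens[k], bd[which.min(dang)], tolerance = 1e-3)
      }
    }
  })
})

test_that("the nucleator on a great-circle profile recovers the sphere exactly", {
  prof <- data.frame(id = 1, section = 1, area = pi * 25)
  prof$polygon <- list(circlePolygon(r = 5, n = 4000))
  est <- nucleatorEstimates(prof, variant = "largest", seed = 1)
  expect_equal(est$volume, 4 / 3 * pi * 125, tolerance = 1e-3) # 523.60
  expect_equal(est$diameter, 10, tolerance = 1e-3)
})

test_that("all-profiles underestimates the largest-profile mean on a sphere stack", {
  # profiles of a sphere of radius 5 sectioned at 1 um spacing
  zs <- seq(-4.5, 4.5, by = 1)
  rad <- sqrt(25 - zs^2)
  prof <- data.frame(id = 1, section = seq_along(zs), area = pi * rad^2)
  prof$polygon <- lapply(rad, function(r) circlePolygon(r = r, n = 720))
  eL <- nucleatorEstimates(prof, "largest", seed = 2)
  eA <- nucleatorEstimates(prof, "all", seed = 2)
  expect_lt(eA$meanRayLength, eL$meanRayLength)
  expect_lt(eA$volume, eL$volume)
  # classical variant uses the mean of cubed lengths
  eC <- nucleatorEstimates(prof, "all", seed = 2, classical = TRUE)
  expect_gt(eC$volume, eA$volume)
})

test_that("ray lengths are invariant to vertex order and rigid rotation", {
  poly <- squarePolygon(4)
  l1 <- profileRayLengths(poly, nRays = 5, startAngle = 10)
  l2 <- profileRayLengths(poly[rev(seq_len(nrow(poly))), ], nRays = 5,
                          startAngle = 10)
  expect_equal(l1, l2, tolerance = 1e-12)
  # rotating the profile and the start angle together gives the same lengths
  rot <- 33 * pi / 180
  R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2)
  l3 <- profileRayLengths(t(R %*% t(poly)), nRays = 5, startAngle = 10 + 33)
  expect_equal(l1, l3, tolerance = 1e-9)
})

test_that("a centroid outside a pathological profile is flagged", {
  # crescent-like polygon whose area centroid falls outside
  th <- seq(-2.2, 2.2, length.out = 60)
  outer <- cbind(5 * cos(th), 5 * sin(th))
  inner <- cbind(4.6 * cos(rev(th)), 4.6 * sin(rev(th)))
  poly <- rbind(outer, inner)
  expect_error(profileRayLengths(poly), "skipped")
})

test_that("sphere-equivalent diameter inverts the sphere volume", {
  expect_equal(sphereEquivalentDiameter(4188.790205), 20, tolerance = 1e-6)
  expect_equal(sphereEquivalentDiameter(523.5987756), 10, tolerance = 1e-6)
  expect_equal(sphereEquivalentDiameter(795), 11.49, tolerance = 1e-3)
  expect_error(sphereEquivalentDiameter(-1), "positive")
})
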