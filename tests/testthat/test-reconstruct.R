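test_that("component filters follow the voxel-count and section-span rules", {
  a <- array(0, c(20, 20, 10))
  a[2:3, 2:3, 2:4] <- 1   # 12 voxels  -> kept
  a[10:11, 10:11, 3] <- 1 # 4 voxels   -> dropped (< 8)
  lab <- labelAndFilter(MaskStack(a, c(1, 1, 1)), minVoxels = 8)
  expect_equal(max(stackData(lab)), 1)

  b <- array(0, c(20, 20, 10))
  b[5:8, 5:8, 5:7] <- 1   # spans 3 sections -> dropped in validation mode
  lab2 <- labelAndFilter(MaskStack(b, c(1, 1, 1)), minVoxels = 1,
                         minConsecutiveSections = 4)
  expect_equal(max(stackData(lab2)), 0)
  lab3 <- labelAndFilter(MaskStack(b, c(1, 1, 1)), minVoxels = 1,
                         minConsecutiveSections = 3)
  expect_equal(max(stackData(lab3)), 1)

  bad <- a; bad[1] <- 0.5
  expect_error(labelAndFilter(bad, spacing = c(1, 1, 1)), "non-binary")
})

test_that("labelling agrees with a brute-force flood fill (26-connectivity)", {
  withr::with_seed(31, {
    a <- array(rbinom(12 * 12 * 6, 1, 0.25), c(12, 12, 6))
  })
  lab <- stackData(labelAndFilter(MaskStack(a, c(1, 1, 1)), minVoxels = 1,
                                  dropEdgeSections = 0))
  # oracle: BFS flood fill
  d <- dim(a)
  oracle <- array(0L, d)
  nxt <- 0L
  for (idx in which(a > 0)) {
    if (oracle[idx] > 0) next
    nxt <- nxt + 1L
    queue <- idx
    oracle[idx] <- nxt
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      i <- ((cur - 1) %% d[1]) + 1
      j <- (((cur - 1) %/% d[1]) %% d[2]) + 1
      k <- ((cur - 1) %/% (d[1] * d[2])) + 1
      for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
        if (di == 0 && dj == 0 && dk == 0) next
        ii <- i + di; jj <- j + dj; kk <- k + dk
        if (ii < 1 || jj < 1 || kk < 1 || ii > d[1] || jj > d[2] || kk > d[3])
          next
        nidx <- ii + (jj - 1) * d[1] + (kk - 1) * d[1] * d[2]
        if (a[nidx] > 0 && oracle[nidx] == 0L) {
          oracle[nidx] <- nxt
          queue <- c(queue, nidx)
        }
      }
    }
  }
  # same partition (label values may permute)
  expect_equal(max(lab), max(oracle))
  for (L in seq_len(max(oracle))) {
    expect_equal(length(unique(lab[oracle == L])), 1)
  }
})

test_that("digitised ball morphometry matches the analytic sphere", {
  for (sp in list(c(0.5, 0.5, 0.5), c(0.272, 0.272, 0.9))) {
    cells <- measureCells(ballVolume(10, sp), computeProfiles = FALSE)$cells
    expect_equal(cells$volume, 4 / 3 * pi * 1000, tolerance = 0.02)
    expect_gte(cells$sphericity, 0.97)
  }
})

test_that("cube sphericity approaches the closed form (pi/6)^(1/3)", {
  cells <- measureCells(cubeVolume(20, 0.5), computeProfiles = FALSE)$cells
  expect_equal(cells$sphericity, (pi / 6)^(1 / 3), tolerance = 0.05)
  expect_equal(cells$volume, 20^3, tolerance = 1e-9)
})

test_that("prolate ellipsoid sphericity matches the spheroid closed form", {
  cells <- measureCells(ellipsoidVolume(c(10, 2, 2)),
                        computeProfiles = FALSE)$cells
  psiTrue <- pi^(1 / 3) * (6 * 4 / 3 * pi * 40)^(2 / 3) /
    spheroidSurfaceArea(10, 2)
  expect_equal(psiTrue, 0.732, tolerance = 1e-3)
  expect_equal(cells$sphericity, psiTrue, tolerance = 0.05)
  # the long axis is x, so the Feret orientation should be almost 0 deg
  expect_lt(cells$thetaDeg, 3)
  expect_equal(cells$feret3d, 20, tolerance = 0.05)
})

test_that("sphericity is invariant under uniform rescaling of the spacing", {
  ball <- ballVolume(10, c(0.5, 0.5, 0.5))
  scaled <- LabelVolume(stackData(ball), 3 * voxelSpacing(ball))
  m1 <- measureCells(ball, computeProfiles = FALSE)$cells
  m2 <- measureCells(scaled, computeProfiles = FALSE)$cells
  expect_equal(m2$volume, 27 * m1$volume, tolerance = 1e-9)
  expect_equal(m2$surface, 9 * m1$surface, tolerance = 1e-9)
  expect_equal(m2$sphericity, m1$sphericity, tolerance = 1e-9)
})

test_that("orientation from Feret endpoints folds into [0, 90] degrees", {
  o <- feretOrientation(c(0, 0, 0), c(5, 0, 0))
  expect_equal(o$u, c(1, 0, 0))
  expect_equal(o$theta, 0)
  expect_equal(feretOrientation(c(0, 0, 0), c(0, 3, 0))$theta, 90)
  expect_equal(feretOrientation(c(0, 0, 0), c(1, 1, 0))$theta, 45)
  # sign-flip gives the same folded angle
  expect_equal(feretOrientation(c(0, 0, 0), c(-1, -1, 0))$theta, 45)
  expect_error(feretOrientation(c(1, 1, 1), c(1, 1, 1)), "degenerate")
})

test_that("3D max Feret dominates every per-section 2D Feret", {
  sc <- simulateScene(sceneParams(windowBox = c(60, 60, 40), columnIntensity = 2.5e-3,
                                  pointsPerColumnMean = 8, seed = 12))
  meas <- measureCells(sc@truthLabels)
  for (r in seq_len(nrow(meas$cells))) {
    f2 <- meas$profiles$feret2d[meas$profiles$id == meas$cells$id[r]]
    expect_gte(meas$cells$feret3d[r] + 1e-9, max(f2))
  }
})
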