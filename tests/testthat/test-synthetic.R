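test_that("zero column intensity yields an empty pattern; degenerate windows fail", {
  p <- sceneParams(columnIntensity = 0)
  expect_equal(npoints(simulateColumnarPattern(p, seed = 1)), 0)
  expect_error(sceneParams(windowBox = c(0, 10, 10)), "degenerate")
  expect_error(simulateCSRPattern(n = -1, windowBox = c(1, 1, 1)),
               "non-negative")
})

test_that("the compound-Poisson mean count matches the analytic value", {
  p <- sceneParams(windowBox = c(50, 100, 100), columnIntensity = 1e-3,
                   pointsPerColumnMean = 20, hardcoreDistance = 0)
  ns <- vapply(1:200, function(s)
    npoints(simulateColumnarPattern(p, seed = s)), numeric(1))
  expected <- 1e-3 * 100 * 100 * 20  # 200
  # var of a Poisson cluster process: lambda_c A (m + m^2)
  mcsd <- sqrt(1e-3 * 100 * 100 * (20 + 400) / 200)
  expect_lt(abs(mean(ns) - expected), 3 * mcsd)
})

test_that("hardcore thinning enforces the minimum pairwise distance", {
  p <- sceneParams(windowBox = c(100, 100, 100), columnIntensity = 2e-3,
                   pointsPerColumnMean = 10, columnRadiusSD = 5,
                   hardcoreDistance = 10)
  pat <- simulateColumnarPattern(p, seed = 3)
  expect_gt(npoints(pat), 2)
  expect_gte(min(dist(patternCoords(pat))), 10)
})

test_that("CSR moments: uniform means and Poisson count variance", {
  pat <- simulateCSRPattern(n = 1e4, windowBox = c(1, 1, 1), seed = 2)
  xyz <- patternCoords(pat)
  se <- 1 / sqrt(12 * 1e4)  # sd of the mean of U(0,1)
  expect_true(all(abs(colMeans(xyz) - 0.5) < 3 * se))
  expect_equal(npoints(simulateCSRPattern(n = 0, windowBox = c(1, 1, 1))), 0)

  ns <- vapply(1:400, function(s)
    npoints(simulateCSRPattern(intensity = 50, windowBox = c(1, 1, 1),
                               seed = s)), numeric(1))
  # variance of a Poisson(50) count, chi-square slack on 400 draws
  expect_lt(abs(var(ns) - 50), 4 * 50 * sqrt(2 / 399))
})

test_that("intensity estimation is unbiased under CSR across seeds", {
  lam <- 5e-4
  est <- vapply(1:500, function(s)
    patternIntensity(simulateCSRPattern(intensity = lam,
                                        windowBox = c(50, 50, 50),
                                        seed = 9000 + s)), numeric(1))
  mcsd <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - lam), 3 * mcsd)
})

test_that("cell synthesis solves spheroid geometry in closed form", {
  # sphere request: sphericity 1 at the sphere volume gives radius 10
  pat <- PointPattern3D(rbind(c(25, 25, 25)), c(50, 50, 50))
  p <- sceneParams(targetSphericityMean = 1, targetSphericitySD = 0,
                   cellVolumeMean = 4188.790205, cellVolumeLogSD = 1e-9,
                   smallRoundFraction = 0)
  cell <- synthesizeCells(pat, p, seed = 1)
  expect_equal(unlist(cell[, c("a", "b", "c")]), c(a = 10, b = 10, c = 10),
               tolerance = 1e-4)

  # prolate request: psi = 0.733 at V = 167.55 gives semi-axes (10, 2, 2)
  p2 <- sceneParams(targetSphericityMean = 0.7330, targetSphericitySD = 0,
                    cellVolumeMean = 167.5516, cellVolumeLogSD = 1e-9,
                    smallRoundFraction = 0)
  cell2 <- synthesizeCells(pat, p2, seed = 1)
  expect_equal(cell2$a, 10, tolerance = 0.02)
  expect_equal(cell2$b, 2, tolerance = 0.02)

  expect_error(synthesizeCells(pat, sceneParams(targetSphericityMean = 1.2)),
               "unsatisfiable")
})

test_that("zero orientation concentration aligns every cell with the x-axis", {
  pat <- simulateCSRPattern(n = 40, windowBox = c(60, 60, 60), seed = 6)
  cells <- synthesizeCells(pat, sceneParams(orientationConcentration = 0,
                                            smallRoundFraction = 0), seed = 2)
  expect_true(all(cells$ux == 1 & cells$uy == 0 & cells$uz == 0))
})

test_that("scenes are bit-identical under a fixed seed", {
  s1 <- simulateScene(sceneParams(windowBox = c(40, 40, 30), columnIntensity = 2e-3,
                                  pointsPerColumnMean = 6, seed = 21))
  s2 <- simulateScene(sceneParams(windowBox = c(40, 40, 30), columnIntensity = 2e-3,
                                  pointsPerColumnMean = 6, seed = 21))
  expect_identical(stackData(s1@stack), stackData(s2@stack))
  expect_identical(s1@cells, s2@cells)
})

test_that("a noise- and blur-free stack is exactly two-valued", {
  sc <- simulateScene(sceneParams(windowBox = c(40, 40, 30), columnIntensity = 2e-3,
                                  pointsPerColumnMean = 6, psfSigma = 0,
                                  noiseSD = 0, seed = 8))
  expect_setequal(unique(as.vector(stackData(sc@stack))), c(60, 200))
})

test_that("voxelised volumes converge to the analytic ellipsoid volumes", {
  # single 10-um ball at the published anisotropic spacing
  pat <- PointPattern3D(rbind(c(30, 30, 30)), c(60, 60, 60))
  p <- sceneParams(windowBox = c(60, 60, 60), targetSphericityMean = 1,
                   targetSphericitySD = 0, cellVolumeMean = 4188.790205,
                   cellVolumeLogSD = 1e-9, smallRoundFraction = 0,
                   voxelSpacing = c(0.272, 0.272, 0.9), psfSigma = 0,
                   noiseSD = 0)
  cells <- synthesizeCells(pat, p, seed = 3)
  sc <- renderStack(cells, p, seed = 3)
  vox <- sc@cells$voxelCount * prod(p$voxelSpacing)
  expect_equal(vox, 4188.790205, tolerance = 0.02)

  # scene-wide at default spacing: total voxel volume within 3 percent
  scd <- simulateScene(sceneParams(windowBox = c(60, 60, 40), columnIntensity = 1e-3,
                                   pointsPerColumnMean = 8, seed = 14))
  voxTot <- sum(scd@cells$voxelCount) * prod(scd@params$voxelSpacing)
  anaTot <- sum(scd@cells$volume)
  overlap <- length(scd@notes) > 0
  expect_equal(voxTot, anaTot, tolerance = if (overlap) 0.08 else 0.03)

  # halving the spacing roughly halves the voxelisation error
  pFine <- p; pFine$voxelSpacing <- c(0.136, 0.136, 0.45)
  scf <- renderStack(cells, pFine, seed = 3)
  errC <- abs(vox - 4188.790205)
  errF <- abs(scf@cells$voxelCount * prod(pFine$voxelSpacing) - 4188.790205)
  expect_lt(errF, errC)
})

test_that("scene export writes readable text and image artefacts", {
  sc <- simulateScene(sceneParams(windowBox = c(30, 30, 20), columnIntensity = 4e-3,
                                  pointsPerColumnMean = 5, seed = 4))
  dir <- withr::local_tempdir()
  writeScene(sc, dir)
  expect_true(all(file.exists(file.path(dir, c("stack.tif", "labels.tif",
                                               "cells.csv", "pattern.csv",
                                               "window.yaml", "params.yaml")))))
  st <- readStackTIFF(file.path(dir, "stack.tif"),
                      spacing = sc@params$voxelSpacing)
  expect_equal(dim(st), dim(sc@stack))
  pat <- readPointPatternCSV(file.path(dir, "pattern.csv"),
                             file.path(dir, "window.yaml"))
  expect_equal(npoints(pat), npoints(sc@pattern))
  expect_equal(patternCoords(pat), patternCoords(sc@pattern),
               tolerance = 1e-12)
})
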