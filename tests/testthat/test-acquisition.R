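test_that("quartile rows of a uniform sample area sit at 25/50/75 percent", {
  img <- matrix(1, 100, 100)
  roi <- cbind(c(0.5, 100.5, 100.5, 0.5), c(0.5, 0.5, 100.5, 100.5))
  plan <- planBiopsies(img, roi, biopsyDiameterPx = 11, seed = 1)
  expect_equal(plan@quartileRows, c(25L, 50L, 75L))
  expect_true(all(plan@quarters %in% c(1L, 3L)) ||
                all(plan@quarters %in% c(2L, 4L)))
  # chosen points lie inside the eroded mask
  for (q in 1:2) {
    expect_equal(plan@erodedMask[plan@chosenPoints[q, 1],
                                 plan@chosenPoints[q, 2]], 1)
  }
})

test_that("a thin stripe is annihilated by erosion with a wide biopsy", {
  img <- matrix(0, 100, 100)
  img[, 41:60] <- 1  # 20 px wide stripe
  roi <- cbind(c(0.5, 100.5, 100.5, 0.5), c(0.5, 0.5, 100.5, 100.5))
  expect_error(planBiopsies(img, roi, biopsyDiameterPx = 40, seed = 1),
               "too small")
})

test_that("erosion equals brute-force per-pixel disk testing", {
  withr::with_seed(17, {
    img <- matrix(0, 48, 48)
    img[10:40, 8:44] <- 1
    img[sample(48 * 48, 250)] <- 0  # punch holes
  })
  roi <- cbind(c(0.5, 48.5, 48.5, 0.5), c(0.5, 0.5, 48.5, 48.5))
  d <- 9; r <- floor(d / 2)
  plan <- planBiopsies(img, roi, biopsyDiameterPx = d, seed = 2)
  oracle <- matrix(0, 48, 48)
  for (i in 1:48) for (j in 1:48) {
    ok <- TRUE
    for (di in -r:r) for (dj in -r:r) {
      if (di^2 + dj^2 > r^2) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || jj < 1 || ii > 48 || jj > 48 ||
          plan@sampleMask[ii, jj] == 0) { ok <- FALSE; break }
    }
    if (ok) oracle[i, j] <- 1
  }
  expect_equal(plan@erodedMask, oracle)
})

test_that("biopsy planning is deterministic given the seed", {
  img <- matrix(1, 60, 60)
  roi <- cbind(c(0.5, 60.5, 60.5, 0.5), c(0.5, 0.5, 60.5, 60.5))
  p1 <- planBiopsies(img, roi, 7, seed = 99)
  p2 <- planBiopsies(img, roi, 7, seed = 99)
  expect_identical(p1@chosenPoints, p2@chosenPoints)
  expect_identical(p1@quarters, p2@quarters)
})

test_that("a constant montage contains no sections", {
  expect_warning(det <- detectSections(matrix(0.4, 120, 160)), "no sections")
  expect_equal(nrow(det@boxes), 0)
})

test_that("textured rectangles are detected in reading order", {
  fx <- montageFixture()
  det <- detectSections(fx$montage, minArea = 2000)
  expect_equal(nrow(det@boxes), 6)
  for (k in 1:6) {
    truth <- fx$boxes[[fx$readingOrder[k]]]
    # detected box within a small margin of the ground-truth rectangle
    expect_lt(abs(det@boxes$r0[k] - truth["r0"]), 8)
    expect_lt(abs(det@boxes$c0[k] - truth["c0"]), 8)
    expect_lt(abs(det@boxes$r1[k] - truth["r1"]), 8)
    expect_lt(abs(det@boxes$c1[k] - truth["c1"]), 8)
  }
  # systematic sampling: every 2nd section keeps 1, 3, 5
  det2 <- detectSections(fx$montage, minArea = 2000, everyK = 2)
  expect_equal(nrow(det2@boxes), 3)
  expect_equal(det2@boxes$r0, det@boxes$r0[c(1, 3, 5)])
})

test_that("detected sections export as one readable TIFF each", {
  fx <- montageFixture()
  det <- detectSections(fx$montage, minArea = 2000)
  dir <- withr::local_tempdir()
  paths <- writeSections(det, fx$montage, dir)
  expect_length(paths, 6)
  expect_true(all(file.exists(paths)))
  back <- tiff::readTIFF(paths[1])
  expect_equal(dim(back),
               c(det@boxes$r1[1] - det@boxes$r0[1] + 1,
                 det@boxes$c1[1] - det@boxes$c0[1] + 1))
})

test_that("section detection is invariant to background padding", {
  fx <- montageFixture()
  det <- detectSections(fx$montage, minArea = 2000)
  padded <- matrix(0.5, nrow(fx$montage) + 40, ncol(fx$montage) + 60)
  padded[21:(20 + nrow(fx$montage)), 31:(30 + ncol(fx$montage))] <- fx$montage
  detP <- detectSections(padded, minArea = 2000)
  expect_equal(nrow(detP@boxes), nrow(det@boxes))
  expect_equal(detP@boxes$r0 - 20, det@boxes$r0, tolerance = 2)
  expect_equal(detP@boxes$c0 - 30, det@boxes$c0, tolerance = 2)
})

test_that("identical images register to the identity", {
  img <- texturedImage(128, seed = 2)
  al <- alignStack(list(img, img), downscale = 4)
  tr <- al$transforms[[2]]
  expect_lt(abs(tr@angle), 0.1)
  expect_lt(abs(tr@dx), 0.5)
  expect_lt(abs(tr@dy), 0.5)
})

test_that("a known rotation and shift are recovered within tolerance", {
  img <- texturedImage(192, seed = 3)
  moved <- CortexMorph:::.resampleRigid(img, -3, -10, 5, fill = median(img))
  # moving `moved` by (3, 10, -5) brings it back onto img
  al <- alignStack(list(img, moved), downscale = 4)
  tr <- al$transforms[[2]]
  expect_lt(abs(tr@angle - 3), 0.2)
  expect_lt(abs(tr@dx - 10), 1)
  expect_lt(abs(tr@dy + 5), 1)
})

test_that("alignment improves pairwise correlation of a jittered stack", {
  base <- texturedImage(128, seed = 8)
  withr::with_seed(30, {
    imgs <- lapply(1:6, function(k) {
      CortexMorph:::.resampleRigid(base, runif(1, -2, 2), runif(1, -4, 4),
                                   runif(1, -4, 4), fill = median(base))
    })
  })
  ncc <- function(stack) {
    v <- sapply(1:(length(stack) - 1), function(k)
      cor(as.vector(stack[[k]]), as.vector(stack[[k + 1]])))
    mean(v)
  }
  al <- alignStack(imgs, downscale = 4)
  aligned <- lapply(1:6, function(k) stackData(al$aligned)[, , k])
  expect_gt(ncc(aligned), ncc(imgs))
})

test_that("aligning an aligned stack is idempotent within tolerance", {
  img <- texturedImage(128, seed = 13)
  moved <- CortexMorph:::.resampleRigid(img, -2, -6, 4, fill = median(img))
  al <- alignStack(list(img, moved), downscale = 4)
  aligned <- lapply(1:2, function(k) stackData(al$aligned)[, , k])
  al2 <- alignStack(aligned, downscale = 4)
  tr <- al2$transforms[[2]]
  expect_lt(abs(tr@angle), 0.1)
  expect_lt(abs(tr@dx), 0.5)
  expect_lt(abs(tr@dy), 0.5)
})
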