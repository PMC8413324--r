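test_that("layer III is located between two dense bands", {
  withr::with_seed(40, {
    x <- c(rnorm(400, 100, 12), rnorm(400, 400, 12), runif(250, 130, 370))
  })
  lw <- selectLayer3(x, mode = "auto")
  expect_gt(lw@bounds[1], 100)
  expect_lt(lw@bounds[2], 400)
  # the sparse mid-zone (density minimum) is inside the window
  expect_lt(lw@bounds[1], 250)
  expect_gt(lw@bounds[2], 250)
})

test_that("uniform centroids leave the layers unresolvable", {
  withr::with_seed(41, x <- runif(500, 0, 500))
  expect_error(selectLayer3(x, mode = "auto", bw = 120), "not resolvable")
  # with manual bounds supplied the call falls back instead of failing
  lw <- selectLayer3(x, mode = "auto", manualBounds = c(120, 380), bw = 120)
  expect_equal(lw@bounds, c(120, 380))
  expect_equal(lw@mode, "manual")
})

test_that("manual bounds pass through unchanged", {
  lw <- selectLayer3(runif(150, 0, 500), mode = "manual",
                     manualBounds = c(120, 380))
  expect_equal(lw@bounds, c(120, 380))
})

test_that("the mixture separates well-separated volume/sphericity clusters", {
  withr::with_seed(50, {
    big <- cbind(rnorm(500, 800, 150), rnorm(500, 0.35, 0.04))
    small <- cbind(rnorm(300, 150, 30), rnorm(300, 0.70, 0.04))
  })
  cells <- data.frame(volume = c(big[, 1], small[, 1]),
                      sphericity = c(big[, 2], small[, 2]),
                      truth = rep(c("pyramidal", "non_pyramidal"),
                                  c(500, 300)))
  res <- gmmSplit(cells, seed = 1)
  expect_gte(mean(res$labels == cells$truth), 0.99)
  expect_equal(res$excludedFraction, 0.375, tolerance = 0.02)
  # ordering invariance: shuffling rows permutes labels identically
  withr::with_seed(51, perm <- sample(nrow(cells)))
  res2 <- gmmSplit(cells[perm, ], seed = 1)
  expect_gte(mean(res2$labels == cells$truth[perm]), 0.99)
})

test_that("the in-package EM agrees with a reference mixture fitter", {
  skip_if_not_installed("mclust")
  suppressMessages(require(mclust, quietly = TRUE))
  withr::with_seed(52, {
    X <- rbind(cbind(rnorm(250, 700, 80), rnorm(250, 0.4, 0.05)),
               cbind(rnorm(150, 150, 30), rnorm(150, 0.75, 0.05)))
  })
  own <- CortexMorph:::.fitGMM2(X, seed = 3)
  ref <- mclust::Mclust(X, G = 2, modelNames = "VVV", verbose = FALSE)
  agree <- max(mean(own$cluster == ref$classification),
               mean(own$cluster == 3 - ref$classification))
  expect_gte(agree, 0.98)
})

test_that("all above-mean cells stay pyramidal and ties break deterministically", {
  withr::with_seed(53, {
    v <- c(rlnorm(200, log(600), 0.5), rlnorm(100, log(100), 0.3))
    s <- c(rnorm(200, 0.5, 0.05), rnorm(100, 0.9, 0.03))
  })
  cells <- data.frame(volume = v, sphericity = s)
  res <- gmmSplit(cells, seed = 2)
  expect_true(all(res$labels[cells$volume >= mean(cells$volume)] ==
                    "pyramidal"))
  # duplicated tight cluster: degenerate but deterministic
  dup <- data.frame(volume = rep(c(100, 101, 102, 99, 100.5), 10),
                    sphericity = rep(c(0.5, 0.51, 0.49, 0.48, 0.52), 10))
  r1 <- gmmSplit(dup, seed = 4)
  r2 <- gmmSplit(dup, seed = 4)
  expect_identical(r1$labels, r2$labels)
  expect_error(gmmSplit(data.frame(volume = rep(c(1, 2, 3), 20),
                                   sphericity = rep(0.5, 60)), seed = 1),
               "degenerate")
})

test_that("log-Feret screening flags planted giants, upper tail only", {
  withr::with_seed(60, {
    n <- 1000
    f3 <- rlnorm(n, log(20), 0.2)
    f2 <- rlnorm(n, log(12), 0.2)
  })
  cells <- data.frame(feret3d = c(f3, 10 * max(f3)),
                      feret2dMax = c(f2, 10 * max(f2)))
  labels <- rep("pyramidal", n + 1)
  out <- outlierFilter(cells, labels)
  expect_equal(out[n + 1], "outlier")
  # a tiny cell is never flagged (upper tail only)
  cells2 <- data.frame(feret3d = c(f3, min(f3) / 10),
                       feret2dMax = c(f2, min(f2) / 10))
  out2 <- outlierFilter(cells2, labels)
  expect_equal(out2[n + 1], "pyramidal")
  # identical Feret values: SD = 0, no outliers
  cells3 <- data.frame(feret3d = rep(5, 50), feret2dMax = rep(3, 50))
  expect_true(all(outlierFilter(cells3, rep("pyramidal", 50)) == "pyramidal"))
})

test_that("the pure log-normal false-flag rate matches the Gaussian tail", {
  withr::with_seed(61, {
    n <- 1e4
    cells <- data.frame(feret3d = rlnorm(n, log(20), 0.25),
                        feret2dMax = rlnorm(n, log(12), 0.25))
  })
  out <- outlierFilter(cells, rep("pyramidal", n))
  frac <- mean(out == "outlier")
  # one-sided 3 sigma, two partially dependent screens: ~0.13-0.3 percent
  expect_gte(frac, 0.0003)
  expect_lte(frac, 0.006)
})

test_that("removing the outlier step can only increase the pyramidal count", {
  withr::with_seed(62, {
    cells <- data.frame(feret3d = rlnorm(200, log(20), 0.4),
                        feret2dMax = rlnorm(200, log(12), 0.4))
  })
  labels <- rep("pyramidal", 200)
  filtered <- outlierFilter(cells, labels)
  expect_lte(sum(filtered == "pyramidal"), sum(labels == "pyramidal"))
})

test_that("number density is plain arithmetic with guarded inputs", {
  expect_equal(numberDensity(100, 0.025), 4000)
  expect_equal(numberDensity(0, 1), 0)
  expect_error(numberDensity(10, 0), "positive")
  expect_error(numberDensity(-1, 1), "non-negative")
})
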