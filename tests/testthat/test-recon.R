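test_that("system matrix rows integrate to the chord length inside the grid", {
  ring <- makeRing(nDetectors = 24L)
  grid <- reconGrid(16L, 64)
  A <- buildSystemMatrix(ring, grid)
  expect_equal(dim(A), c(nLors(24L), 16L * 16L))
  ## geometric oracle: clip each chord to the grid square analytically
  ep <- lorEndpoints(ring)
  half <- 32
  expected <- vapply(seq_len(nLors(24L)), function(l) {
    p0 <- ep$p0[l, ]; p1 <- ep$p1[l, ]
    d <- p1 - p0
    tmin <- 0; tmax <- 1
    for (ax in 1:2) {
      if (d[ax] != 0) {
        tt <- (c(-half, half) - p0[ax]) / d[ax]
        tmin <- max(tmin, min(tt)); tmax <- min(tmax, max(tt))
      } else if (abs(p0[ax]) > half) return(0)
    }
    if (tmin >= tmax) return(0)
    (tmax - tmin) * sqrt(sum(d^2))
  }, numeric(1))
  expect_equal(Matrix::rowSums(A), expected, tolerance = 1e-9)
  ## determinism
  expect_identical(A, buildSystemMatrix(ring, grid))
})

test_that("ML-EM collapses to the data under an identity system", {
  y <- c(3, 9, 0, 5)
  A <- Matrix::Diagonal(4)
  img <- mlem(y, A, 0, reconGrid(2L, 2), nIterations = 1L)
  expect_equal(as.vector(imageValues(img)), y)
  expect_true(all(imageValues(img) >= 0))
})

test_that("ML-EM is monotone in the Poisson likelihood", {
  set.seed(61)
  ring <- makeRing(nDetectors = 24L)
  grid <- reconGrid(12L, 48)
  A <- buildSystemMatrix(ring, grid)
  fTrue <- runif(ncol(A))
  y <- rpois(nrow(A), as.vector(A %*% fTrue) * 5)
  r <- rep(0.2, length(y))
  lls <- numeric(10)
  img <- NULL
  for (k in 1:10) {
    img <- mlem(y, A, r, grid, nIterations = k)
    lls[k] <- mlemLogLik(y, A, img, r)
  }
  expect_true(all(diff(lls) > -1e-8))
})

test_that("expected randoms counts scale rates by the duration", {
  r <- matrix(0, 4, 4); r[1, 2] <- 2.5; r[3, 4] <- 0.12
  est <- new("RandomsEstimate", method = "SP", rates = r, duration = 4,
             intermediate = list())
  rl <- expectedRandomsCounts(est)
  expect_equal(sum(rl), totalRate(est) * 4)
  expect_equal(rl[lorIndex(1, 2, 4)], 10)
  ## real-valued compensation below one count is representable
  expect_true(any(rl > 0 & rl < 1))
})

test_that("figures of merit reproduce their defining identities", {
  grid <- reconGrid(64L, 64)
  ph <- iqPhantom(1e5)
  truth <- trueImage(ph, grid)
  rois <- iqRois(grid)
  ## RoIs are disjoint and interior to homogeneous regions
  expect_equal(length(intersect(rois$hot, rois$warm)), 0L)
  expect_equal(length(intersect(rois$cold, rois$warm)), 0L)
  expect_true(all(truth[rois$cold] == 0))
  expect_equal(sd(truth[rois$hot]), 0)
  expect_equal(sd(truth[rois$warm]), 0)
  ## perfect reconstruction: C = 3, CRC = 1, SOR = 0, RB = 0, IR = 0
  fom <- computeFoms(truth, truth, rois)
  expect_equal(fom$C, 3)
  expect_equal(fom$CRC, 1)
  expect_equal(fom$SOR, 0)
  expect_equal(unname(fom$RB[c("hot", "warm")]), c(0, 0))
  expect_equal(unname(fom$IR[c("hot", "warm")]), c(0, 0))
  ## contrast example: hot mean 4, warm mean 1
  img2 <- truth
  expect_equal(mean(truth[rois$hot]) / mean(truth[rois$warm]) - 1, 3)
})

test_that("correlation coefficient is a scale-free cosine", {
  a <- matrix(runif(16), 4)
  expect_equal(correlationCoefficient(a, a), 1)
  expect_equal(correlationCoefficient(a, 5 * a), 1)
  b <- matrix(0, 4, 4); b[1, 1] <- 1
  c2 <- matrix(0, 4, 4); c2[4, 4] <- 1
  expect_equal(correlationCoefficient(b, c2), 0)
  expect_error(correlationCoefficient(b * 0, c2), "all-zero")
})
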