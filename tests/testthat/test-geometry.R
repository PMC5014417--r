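test_that("ring placement and LoR indexing are consistent", {
  ring <- makeRing()
  expect_equal(nDetectors(ring), 148L)
  a <- detectorAngles(ring)
  expect_equal(a[1], 0)
  expect_equal(a[75], pi)                     # detector opposite detector 1
  expect_equal(tcw(ring), 2 * timeResolutionFwhm(ring))  # tau = 2 x FWHM

  expect_equal(nLors(8), 28L)
  ## bijection over a full small ring and spot checks on the big one
  for (n in c(5L, 8L, 148L)) {
    l <- seq_len(nLors(n))
    ij <- lorPair(l, n)
    expect_true(all(ij[, 1] < ij[, 2]))
    expect_identical(lorIndex(ij[, 1], ij[, 2], n), l)
  }
  expect_error(makeRing(ringDiameter = -1), "positive")
})

test_that("lorThroughPhantom agrees with an exhaustive chord check", {
  ring <- makeRing(nDetectors = 8L)
  ph <- discPhantom(1e4, radius = 0.3 * ringDiameter(ring) / 2)
  got <- lorThroughPhantom(ring, ph)
  ## brute force: minimum distance from the origin-centred disc to each
  ## chord, from the analytic chord midpoint distance
  pos <- detectorPositions(ring)
  expected <- vapply(seq_len(nLors(8L)), function(l) {
    ij <- lorPair(l, 8L)
    p0 <- pos[ij[1], ]; p1 <- pos[ij[2], ]
    d <- p1 - p0
    t <- sum((0 - p0) * d) / sum(d^2)
    t <- min(max(t, 0), 1)
    sqrt(sum((p0 + t * d)^2)) <= 0.3 * ringDiameter(ring) / 2
  }, logical(1))
  expect_identical(got, expected)
  ## a chord through the centre always crosses a centred disc
  expect_true(got[lorIndex(1L, 5L, 8L)])
})

test_that("rate models satisfy the occupancy identity and activity linearity", {
  ring <- makeRing(nDetectors = 32L)
  ph <- iqPhantom(2e5)
  m <- deriveRateModel(ring, ph, nMcRays = 5e4, efficiency = 0.5, seed = 1)
  tot <- rateTotals(m)
  expect_equal(tot[["Lambda"]], tot[["lambda"]] + tot[["rho"]] / 2)
  m2 <- scaleRateModel(m, 2)
  expect_equal(uncorrelatedRates(m2), 2 * uncorrelatedRates(m))
  expect_equal(correlatedRates(m2), 2 * correlatedRates(m))
  ## same seed, doubled activity: identical classification, doubled rates
  m3 <- deriveRateModel(ring, iqPhantom(4e5), nMcRays = 5e4,
                        efficiency = 0.5, seed = 1)
  expect_equal(rateTotals(m3)[["S"]], 2 * tot[["S"]])
})

test_that("photon-pair classification covers the limiting geometries", {
  ring <- makeRing(nDetectors = 32L)
  ## point source at the centre with perfect efficiency: both photons always
  ## reach the ring, so everything is correlated
  m <- deriveRateModel(ring, pointPhantom(1e4), nMcRays = 2e4,
                       efficiency = 1, seed = 2)
  expect_equal(sum(uncorrelatedRates(m)), 0)
  expect_equal(rateTotals(m)[["rho"]], 1e4 * 2, tolerance = 1e-9)
  ## zero efficiency: nothing is detected
  m0 <- deriveRateModel(ring, pointPhantom(1e4), nMcRays = 2e4,
                        efficiency = 0, seed = 2)
  expect_equal(rateTotals(m0)[["S"]], 0)
  ## a source outside the field of view cannot produce correlated singles
  mo <- deriveRateModel(ring, outsideFovPhantom(1e4), efficiency = 0.5)
  expect_equal(sum(correlatedRates(mo)), 0)
  expect_equal(sum(uncorrelatedRates(mo)), 1e4 * 0.5)
  ## phantom poking outside the bore is a geometry error
  expect_error(deriveRateModel(ring, discPhantom(1e4, radius = 60),
                               nMcRays = 1e4),
               "bore")
})

test_that("Monte-Carlo rate model converges with the ray budget", {
  ring <- makeRing(nDetectors = 32L)
  ph <- iqPhantom(1e5)
  m1 <- deriveRateModel(ring, ph, nMcRays = 2e5, efficiency = 0.5, seed = 5)
  m2 <- deriveRateModel(ring, ph, nMcRays = 4e5, efficiency = 0.5, seed = 6)
  t1 <- rateTotals(m1); t2 <- rateTotals(m2)
  expect_lt(abs(t1[["lambda"]] - t2[["lambda"]]) / t2[["lambda"]], 0.01)
  expect_lt(abs(t1[["rho"]] - t2[["rho"]]) / t2[["rho"]], 0.01)
})
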