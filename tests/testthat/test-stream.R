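test_that("model-level streams realise the Poisson superposition", {
  ## all rates zero: empty stream
  m0 <- rateModel(rep(0, 4), matrix(0, 4, 4))
  expect_equal(nrow(events(simulateModelStream(m0, 1, seed = 1))), 0L)

  ## pure uncorrelated: count is Poisson with mean lambda * T
  m <- uniformModel(16L, 1e3)
  counts <- vapply(1:40, function(k)
    nrow(events(simulateModelStream(m, 10, seed = k))), numeric(1))
  expect_lt(abs(mean(counts) - 1e4), 4 * sqrt(1e4))
  ## thinning: per-bin counts of one detector have variance ~ mean
  st <- simulateModelStream(uniformModel(4L, 4e4), 10, seed = 3)
  ev <- events(st)
  bins <- table(cut(ev$time[ev$detector == 1L], breaks = seq(0, 10, 0.5)))
  expect_lt(abs(var(as.numeric(bins)) / mean(as.numeric(bins)) - 1), 0.35)

  ## pure correlated: every single shares its annihilation with exactly one
  ## partner on the other detector, total singles ~ 2 * pair rate * T
  rho <- matrix(0, 8, 8); rho[1, 2] <- 500
  st <- simulateModelStream(rateModel(rep(0, 8), rho), 1, seed = 4)
  ev <- events(st)
  expect_true(all(table(ev$annihilationId) == 2L))
  expect_true(all(sort(unique(ev$detector)) == c(1L, 2L)))
  byId <- split(ev$detector, ev$annihilationId)
  expect_true(all(vapply(byId, function(d) all(sort(d) == c(1L, 2L)),
                         logical(1))))
  expect_lt(abs(nrow(ev) - 1000), 4 * sqrt(1000) * 2)

  ## reproducibility: identical seeds give identical streams
  expect_identical(events(simulateModelStream(m, 1, seed = 9)),
                   events(simulateModelStream(m, 1, seed = 9)))
  expect_error(simulateModelStream(m, -1), "positive")
})

test_that("annihilation-level streams agree with the derived rate model", {
  ring <- makeRing(nDetectors = 32L)
  ph <- iqPhantom(5e4)
  st <- simulateAnnihilationStream(ring, ph, 4, efficiency = 0.5, seed = 11)
  m <- deriveRateModel(ring, ph, nMcRays = 4e5, efficiency = 0.5, seed = 12)
  fw <- modelForwardRates(m, tcw(ring))
  si <- singlesRates(st)
  ## per-detector singles rates match lambda_i + rho_i within 3 SE
  se <- sqrt(fw$Si / 4)
  expect_true(all(abs(si - fw$Si) < 3.5 * se))
  ## perfect efficiency: every annihilation yields exactly two singles
  st2 <- simulateAnnihilationStream(ring, pointPhantom(1e4), 0.5,
                                    efficiency = 1, seed = 13)
  expect_true(all(table(events(st2)$annihilationId) == 2L))
  ## zero activity: empty stream
  ph0 <- iqPhantom(1e-9)
  expect_equal(nrow(events(simulateAnnihilationStream(ring, ph0, 0.001,
                                                      seed = 1))), 0L)
})

test_that("time jitter reproduces the coincidence resolution and keeps order", {
  rho <- matrix(0, 4, 4); rho[1, 2] <- 3e4
  st <- simulateModelStream(rateModel(rep(0, 4), rho), 1, seed = 6)
  expect_identical(applyTimeJitter(st, 0), st)    # fwhm = 0 is a no-op
  fwhm <- 5e-9
  stj <- applyTimeJitter(st, fwhm, seed = 7)
  ev <- events(stj)
  expect_false(is.unsorted(ev$time))              # re-sorted
  dt <- vapply(split(ev$time, ev$annihilationId), function(t)
    diff(range(t)), numeric(1))
  ## |dt| is half-normal; FWHM of the signed difference is 2.355 * sd
  fwhmHat <- 2 * sqrt(2 * log(2)) * sqrt(mean(dt^2))
  expect_lt(abs(fwhmHat - fwhm) / fwhm, 0.05)
})

test_that("paralysable dead time removes events per the throughput law", {
  ## two events 100 ns apart with 300 ns dead time: second removed
  st <- makeStream(c(0, 100e-9), c(1L, 1L), duration = 1)
  expect_equal(nrow(events(applyDeadTime(st, 300e-9))), 1L)
  ## spacing 350 ns: all kept
  st2 <- makeStream(c(0, 350e-9, 700e-9), c(1L, 1L, 1L), duration = 1)
  expect_equal(nrow(events(applyDeadTime(st2, 300e-9))), 3L)
  ## dead time on one detector does not affect another
  st3 <- makeStream(c(0, 100e-9), c(1L, 2L), duration = 1)
  expect_equal(nrow(events(applyDeadTime(st3, 300e-9))), 2L)
  ## global scope does
  expect_equal(nrow(events(applyDeadTime(st3, 300e-9, scope = "global"))),
               1L)
  ## closed-form paralysable throughput: recorded = n * exp(-n * tau_d)
  for (load in c(0.1, 0.3)) {
    rate <- 5e5
    st <- simulateModelStream(rateModel(rate, matrix(0, 1, 1)), 1,
                              seed = 20 + load * 10)
    rec <- nrow(events(applyDeadTime(st, load / rate)))
    expect_lt(abs(rec - rate * exp(-load)) / (rate * exp(-load)), 0.02)
  }
  expect_error(applyDeadTime(st, 1e-7, model = "nonparalysable"))
})
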