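test_that("the single-window sorter implements the window-walk rules", {
  tau <- 10e-9
  ## three singles inside one window: multiple coincidence, all discarded
  st <- makeStream(c(0, 2e-9, 5e-9), c(1L, 2L, 3L))
  ps <- swSort(st, tau)
  expect_equal(nrow(prompts(ps)), 0L)
  expect_equal(nMultiplesDiscarded(ps), 1L)

  ## prompt then a lone opener: one prompt, no multiple
  st <- makeStream(c(0, 3e-9, 50e-9), c(1L, 6L, 10L))
  ps <- swSort(st, tau)
  expect_equal(nrow(prompts(ps)), 1L)
  expect_equal(prompts(ps)$i, 1L)
  expect_equal(prompts(ps)$j, 6L)
  expect_equal(nMultiplesDiscarded(ps), 0L)

  ## empty stream
  st0 <- makeStream(numeric(0), integer(0), id = integer(0), duration = 1)
  expect_equal(nrow(prompts(swSort(st0, tau))), 0L)

  ## same-detector pairs define no LoR and are discarded but counted
  st <- makeStream(c(0, 3e-9), c(4L, 4L))
  ps <- swSort(st, tau)
  expect_equal(nrow(prompts(ps)), 0L)
  expect_equal(ps@nSameDetector, 1L)
  expect_error(swSort(st, 0), "positive")
})

test_that("sorter output matches the brute-force oracle on random streams", {
  ## spot check; the full 1000-stream sweep runs in the acceptance suite
  set.seed(42)
  tau <- 10e-9
  for (k in 1:100) {
    st <- randomSmallStream(sample(2:50, 1))
    ps <- swSort(st, tau)
    or <- bruteForceSW(events(st)$time, tau)
    det <- events(st)$detector
    keepLor <- det[or$pairs[, 1]] != det[or$pairs[, 2]]
    expected <- data.frame(
      i = pmin(det[or$pairs[keepLor, 1]], det[or$pairs[keepLor, 2]]),
      j = pmax(det[or$pairs[keepLor, 1]], det[or$pairs[keepLor, 2]]),
      windowOpen = events(st)$time[or$pairs[keepLor, 1]])
    expect_equal(prompts(ps)[c("i", "j", "windowOpen")], expected,
                 ignore_attr = TRUE)
    expect_equal(nMultiplesDiscarded(ps), or$nMultiples)
  }
})

test_that("no single is used twice and prompts are bounded", {
  set.seed(1)
  st <- simulateModelStream(uniformModel(16L, 2e5), 0.01, seed = 2)
  ps <- swSort(st, 10e-9)
  expect_lte(nrow(prompts(ps)), nrow(events(st)) %/% 2L)
  expect_equal(sum(promptCounts(ps)), nrow(prompts(ps)))
})

test_that("classification partitions prompts into trues and randoms", {
  rho <- matrix(0, 8, 8); rho[3, 7] <- 2e3
  m <- rateModel(rep(2e3, 8), rho)
  st <- simulateModelStream(m, 1, seed = 5)
  ps <- classifyPrompts(swSort(st, 10e-9))
  expect_true(ps@labeled)
  expect_equal(sum(trueCounts(ps)) + sum(randomCounts(ps)),
               nrow(prompts(ps)))
  expect_equal(trueCounts(ps) + randomCounts(ps), promptCounts(ps))
  ## a prompt from one correlated pair is a true; trues all live on (3, 7)
  expect_gt(trueCounts(ps)[3, 7], 0)
  expect_equal(sum(trueCounts(ps)) , trueCounts(ps)[3, 7])
  ## unlabeled stream cannot be classified
  stU <- makeStream(c(0, 1e-9), c(1L, 2L), id = c(-1L, -1L))
  expect_error(classifyPrompts(swSort(stU, 10e-9)), "labeled")
})

test_that("delayed-window sorting extracts cross coincidences only", {
  tau <- 10e-9; delay <- 500e-9
  ## events at 0 and 505 ns: the delayed copy of the first lands in the
  ## window opened by the second
  st <- makeStream(c(0, 505e-9), c(2L, 8L), duration = 1)
  dw <- dwSort(st, tau, delay)
  expect_equal(totalRate(dw), 1)
  expect_equal(lorRates(dw)[2, 8], 1)
  ## periodic stream with period 600 ns: nothing falls in any delayed window
  st2 <- makeStream(seq(0, 6e-6, by = 600e-9), rep(c(1L, 5L), length.out = 11),
                    duration = 1)
  expect_equal(totalRate(dwSort(st2, tau, delay)), 0)
  expect_error(dwSort(st, tau, 5e-9), "delay")
})

test_that("DW total matches the ideal randoms rate on uncorrelated streams", {
  m <- uniformModel(148L, 1.5e5)
  dws <- numeric(30); r0s <- numeric(30)
  for (k in 1:30) {
    st <- simulateModelStream(m, 0.5, seed = childSeed(3, k))
    dws[k] <- totalRate(dwSort(st, 10e-9, 500e-9))
    r0s[k] <- totalRate(estimateIdeal(classifyPrompts(swSort(st, 10e-9))))
  }
  se <- sqrt(var(dws) / 30 + var(r0s) / 30)
  expect_lt(abs(mean(dws) - mean(r0s)), 3 * se)
})
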