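tau <- 10e-9

test_that("singles rates are raw counts over duration", {
  st <- makeStream(runif(1000, 0, 1), rep(3L, 1000), duration = 1,
                   nDetectors = 4L)
  si <- singlesRates(st)
  expect_equal(si, c(0, 0, 1000, 0))
  st0 <- makeStream(numeric(0), integer(0), id = integer(0), duration = 1,
                    nDetectors = 4L)
  expect_equal(singlesRates(st0), rep(0, 4))
})

test_that("SR estimate is the textbook 2 tau Si Sj", {
  est <- estimateSR(c(1e5, 1e5, 0), tau)
  expect_equal(lorRates(est)[1, 2], 200)
  expect_equal(lorRates(est)[1, 3], 0)
  expect_equal(lorRates(est)[2, 3], 0)
  expect_equal(totalRate(est), 200)
})

test_that("the pile-up equation solver finds the physical root", {
  ## zero window degenerates to lambda = S - P
  expect_equal(solveLambda(1000, 100, 0), 900)
  ## no prompts: root of 2 tau lambda^2 - lambda + S = 0 (quadratic formula)
  S <- 1e5
  lam <- solveLambda(S, 0, tau)
  quad <- (1 - sqrt(1 - 8 * tau * S)) / (4 * tau)
  expect_equal(lam, quad, tolerance = 1e-10)
  ## pathological inputs carry diagnostics
  expect_error(solveLambda(1000, 2000, 0), "root")
})

test_that("forward-constructed rates invert to the exact lambda", {
  ## single deterministic round trip at the documented working point
  m <- uniformModel(148L, 4e5, pairTotal = 5e4)   # rho singles = 1e5
  fw <- modelForwardRates(m, tau)
  expect_equal(fw$S, 5e5)
  lam <- solveLambda(fw$S, fw$doubledPromptsRate, tau)
  expect_lt(abs(lam - 4e5) / 4e5, 1e-9)
})

test_that("effective parameters satisfy the model identities", {
  ## lambda = 0 substitution
  ep <- effectiveParams(0, 1e5, c(2e4, 3e4), c(10, 20), tau)
  expect_equal(ep$tauEff, tau * exp(-tau * 1e5))
  expect_equal(ep$sEff, c(2e4, 3e4) - c(10, 20) * exp(tau * 1e5))
  ## on exact forward-model inputs the effective singles recover the
  ## uncorrelated rates up to the pile-up factor: sEff = lambda_i (1 - 2 tau lambda)
  m <- uniformModel(64L, 3e5, pairTotal = 4e4)
  fw <- modelForwardRates(m, tau)
  lam <- solveLambda(fw$S, fw$doubledPromptsRate, tau)
  ep <- effectiveParams(lam, fw$S, fw$Si, fw$Pi, tau)
  lamI <- uncorrelatedRates(m)
  expect_equal(ep$sEff, lamI * (1 - 2 * tau * lam), tolerance = 1e-9)
  expect_error(effectiveParams(1 / (2 * tau), 1e5, 1, 1, tau), "singular")
})

test_that("SP reproduces the closed-form randoms rate on analytic inputs", {
  m <- uniformModel(64L, 3e5, pairTotal = 4e4)
  fw <- modelForwardRates(m, tau)
  lam <- solveLambda(fw$S, fw$doubledPromptsRate, tau)
  ep <- effectiveParams(lam, fw$S, fw$Si, fw$Pi, tau)
  sp <- 2 * ep$tauEff * outer(ep$sEff, ep$sEff)
  oracle <- lorRates(modelRandomsRate(m, tau))
  ut <- upper.tri(oracle)
  expect_equal(sp[ut], oracle[ut], tolerance = 1e-12)
})

test_that("factorised and direct SP forms agree to round-off", {
  set.seed(8)
  for (k in 1:20) {
    n <- 12L
    Si <- runif(n, 1e4, 1e6)
    Pi <- runif(n, 0, Si / 50)
    S <- sum(Si)
    lam <- runif(1, 0.5 * S, 0.99 * S)
    ep <- effectiveParams(lam, S, Si, Pi, tau)
    viaEff <- 2 * ep$tauEff * outer(ep$sEff, ep$sEff)
    direct <- randcoinc:::.spRatesDirect(Si, Pi, lam, S, tau)
    ut <- upper.tri(direct)
    expect_equal(viaEff[ut], direct[ut], tolerance = 1e-14)
  }
})

test_that("SP recovers the SR form when prompts vanish at low rate", {
  n <- 8L
  Si <- rep(1e3, n)                 # tau * S = 8e-5, negligible pile-up
  ps <- swSort(makeStream(numeric(0), integer(0), id = integer(0),
                          duration = 1, nDetectors = n), tau)
  sp <- estimateSP(Si, ps, tau)
  sr <- estimateSR(Si, tau)
  ## agreement up to the O(tau * S) pile-up correction
  expect_equal(totalRate(sp), totalRate(sr), tolerance = 1e-3)
})

test_that("the model oracle evaluates the attenuated product rate", {
  ## 2 tau li lj exp(-2 Lambda tau) with Lambda = 2e5: 200 * exp(-0.004)
  m <- rateModel(c(1e5, 1e5), matrix(0, 2, 2))
  expect_equal(lorRates(modelRandomsRate(m, tau))[1, 2],
               200 * exp(-2 * 2e5 * tau))
  ## doubling lambda quadruples the rate up to the pile-up factor
  m2 <- scaleRateModel(m, 2)
  r1 <- totalRate(modelRandomsRate(m, tau))
  r2 <- totalRate(modelRandomsRate(m2, tau))
  expect_equal(r2 / r1, 4 * exp(-2 * 2e5 * tau), tolerance = 1e-12)
})

test_that("ideal estimate equals labeled random counts over duration", {
  m <- uniformModel(16L, 1e5, pairTotal = 1e3)
  st <- simulateModelStream(m, 0.5, seed = 21)
  ps <- classifyPrompts(swSort(st, tau))
  id <- estimateIdeal(ps)
  expect_equal(totalRate(id), sum(randomCounts(ps)) / 0.5)
  expect_error(estimateIdeal(swSort(st, tau)), "classified")
})

test_that("empirical estimates track the model oracle on simulated streams", {
  ## E[R0] and E[singles] follow the analytic forward model within 3 SE
  m <- uniformModel(32L, 2e5, pairTotal = 1e4)
  r0 <- numeric(25); stot <- numeric(25)
  for (k in 1:25) {
    st <- simulateModelStream(m, 0.5, seed = childSeed(77, k))
    ps <- classifyPrompts(swSort(st, tau))
    r0[k] <- totalRate(estimateIdeal(ps))
    stot[k] <- sum(singlesRates(st))
  }
  oracle <- totalRate(modelRandomsRate(m, tau))
  expect_lt(abs(mean(r0) - oracle), 3 * sd(r0) / sqrt(25))
  expect_lt(abs(mean(stot) - 2.2e5), 3 * sd(stot) / sqrt(25))
})
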