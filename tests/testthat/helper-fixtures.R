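## Shared fixtures and independent oracles for the test suite.

## build a SinglesStream directly from vectors (times in seconds)
makeStream <- function(time, detector, id = seq_along(time),
                       duration = max(time) + 1e-6, nDetectors = 16L) {
  o <- order(time, detector, id)
  new("SinglesStream",
      events = data.frame(time = time[o],
                          detector = as.integer(detector[o]),
                          annihilationId = as.integer(id[o]),
                          photonIndex = rep(0L, length(time))),
      duration = duration, nDetectors = as.integer(nDetectors),
      provenance = list())
}

## uniform rate model: total uncorrelated rate lamTotal spread over n
## detectors, total correlated-pair rate pairTotal spread over all LoRs
uniformModel <- function(n, lamTotal, pairTotal = 0) {
  rho <- matrix(0, n, n)
  if (pairTotal > 0) rho[upper.tri(rho)] <- pairTotal / (n * (n - 1) / 2)
  rateModel(rep(lamTotal / n, n), rho)
}

## Independent brute-force single-window sorter oracle. Walks the event
## list literally as described: take the earliest unconsumed single, open a
## window of length tau, collect every later single with dt <= tau; exactly
## one companion forms a prompt, two or more are a multiple (all consumed),
## none drops the opener. Returns the same shape as the package sorter.
bruteForceSW <- function(time, tau) {
  stopifnot(!is.unsorted(time))
  n <- length(time)
  consumed <- rep(FALSE, n)
  pairs <- list()
  multiples <- 0L
  repeat {
    opener <- which(!consumed)[1L]
    if (is.na(opener)) break
    inside <- which(!consumed & seq_len(n) > opener &
                      time - time[opener] <= tau)
    consumed[opener] <- TRUE
    consumed[inside] <- TRUE
    if (length(inside) == 1L)
      pairs[[length(pairs) + 1L]] <- c(opener, inside)
    else if (length(inside) >= 2L)
      multiples <- multiples + 1L
  }
  list(pairs = do.call(rbind, c(pairs, list(matrix(integer(), 0, 2)))),
       nMultiples = multiples)
}

## random small stream for sorter equivalence checks
randomSmallStream <- function(nEvents, nDet = 8L, span = 200e-9) {
  t <- sort(runif(nEvents, 0, span))
  makeStream(t, sample.int(nDet, nEvents, replace = TRUE),
             id = seq_len(nEvents), duration = span + 1e-9,
             nDetectors = nDet)
}
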