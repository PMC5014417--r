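## Coincidence sorting: single-window (SW) prompts, delayed-window (DW)
## randoms coincidences, and ground-truth classification.

## upper-triangular count matrix from canonical (i, j) prompt pairs
.countMatrix <- function(i, j, n) {
  m <- matrix(0L, n, n)
  if (length(i)) {
    tb <- tabulate(lorIndex(i, j, n), nbins = nLors(n))
    nz <- which(tb > 0L)
    if (length(nz)) m[lorPair(nz, n)] <- tb[nz]
  }
  m
}

#' Single-window coincidence sorter
#'
#' Walks the time-sorted stream with one coincidence window open at a time:
#' an event with no open window opens a window of length `tcw`; when the
#' window closes with exactly one further event inside, the two form a
#' prompt; with two or more the whole group is discarded as a multiple
#' coincidence; with none the opener is dropped. Each single participates
#' in at most one window. Window membership uses a closed boundary
#' (`dt <= tcw`). Prompts whose two singles hit the same detector define no
#' LoR and are discarded (counted in `nSameDetector`).
#'
#' @param stream a [SinglesStream-class] (time-sorted by construction).
#' @param tcw coincidence window tau, s.
#' @return a [PromptSet-class] (unclassified; see [classifyPrompts()]).
#' @examples
#' rm <- rateModel(rep(1e4, 16), matrix(0, 16, 16))
#' ps <- swSort(simulateModelStream(rm, 0.1, seed = 1), 10e-9)
#' @export
swSort <- function(stream, tcw) {
  stopifnot(is(stream, "SinglesStream"))
  if (tcw <= 0) stop("tcw must be positive")
  ev <- stream@events
  n <- stream@nDetectors
  w <- .windowWalk(ev$time, tcw)
  a <- w$a; b <- w$b
  di <- ev$detector[a]; dj <- ev$detector[b]
  same <- di == dj
  nSame <- sum(same)
  a <- a[!same]; b <- b[!same]
  i <- pmin(ev$detector[a], ev$detector[b])
  j <- pmax(ev$detector[a], ev$detector[b])
  pr <- data.frame(
    i = as.integer(i), j = as.integer(j),
    windowOpen = ev$time[a],
    id1 = as.integer(ev$annihilationId[a]),
    id2 = as.integer(ev$annihilationId[b]),
    label = rep("unlabeled", length(a)))
  z <- matrix(0L, n, n)
  new("PromptSet",
      prompts = pr,
      counts = .countMatrix(pr$i, pr$j, n),
      trues = z, randoms = z,
      nMultiples = as.integer(w$nMultiples),
      nSameDetector = as.integer(nSame),
      duration = stream@duration,
      tcw = as.numeric(tcw),
      labeled = FALSE)
}

#' Classify prompts into trues and randoms from ground truth
#'
#' A prompt is a true coincidence iff its two singles share the same
#' annihilation id (by this definition scattered same-annihilation pairs
#' count as trues); otherwise it is a random. Fills the per-LoR trues and
#' randoms count tables; `counts = trues + randoms` exactly.
#'
#' @param promptSet a [PromptSet-class] whose prompts carry annihilation
#'   ids (sorted from a labeled stream).
#' @return the classified [PromptSet-class].
#' @export
classifyPrompts <- function(promptSet) {
  stopifnot(is(promptSet, "PromptSet"))
  pr <- promptSet@prompts
  if (nrow(pr) && any(pr$id1 < 0L | pr$id2 < 0L))
    stop("classification unavailable: stream was not ground-truth labeled")
  n <- nrow(promptSet@counts)
  isTrue <- pr$id1 == pr$id2
  pr$label <- ifelse(isTrue, "true", "random")
  promptSet@prompts <- pr
  promptSet@trues <- .countMatrix(pr$i[isTrue], pr$j[isTrue], n)
  promptSet@randoms <- .countMatrix(pr$i[!isTrue], pr$j[!isTrue], n)
  promptSet@labeled <- TRUE
  validObject(promptSet)
  promptSet
}

#' Delayed-window randoms estimate
#'
#' A copy of the stream shifted by `+delay` is merged with the original and
#' the same single-window walk is run on the merged stream. Only mixed
#' pairs (one original and one delayed single) are retained as delayed
#' coincidences; original-original pairs are prompts (already counted by
#' [swSort()]) and delayed-delayed pairs are their shifted copies, so both
#' are ignored. Windows containing two or more candidate partners are
#' rejected, mirroring the prompt sorter. The per-LoR delayed-coincidence
#' rate is the DW randoms estimate.
#'
#' @param stream a [SinglesStream-class].
#' @param tcw coincidence window, s.
#' @param delay delay, s; must be much larger than `tcw`.
#' @return a [RandomsEstimate-class] with method `"DW"`; the integer
#'   per-LoR delayed counts are kept in `spDiagnostics(x)$counts`.
#' @export
dwSort <- function(stream, tcw, delay) {
  stopifnot(is(stream, "SinglesStream"))
  if (tcw <= 0) stop("tcw must be positive")
  if (delay <= tcw) stop("delay must exceed the coincidence window")
  ev <- stream@events
  n <- stream@nDetectors
  m <- length(ev$time)
  time <- c(ev$time, ev$time + delay)
  det <- c(ev$detector, ev$detector)
  delayed <- c(rep(FALSE, m), rep(TRUE, m))
  o <- order(time, det)
  time <- time[o]; det <- det[o]; delayed <- delayed[o]
  w <- .windowWalk(time, tcw)
  a <- w$a; b <- w$b
  ## keep one orientation only: window opened by a delayed single and
  ## closed by an original one (the original event trails the delayed copy
  ## of its accidental partner by at most tcw). Counting both orientations
  ## would pair the (orig-i, delayed-j) and (orig-j, delayed-i) families
  ## separately and double the estimate relative to the prompt randoms
  ## rate; a hardware delayed channel gates one direction only.
  mixed <- delayed[a] & !delayed[b]
  i <- pmin(det[a[mixed]], det[b[mixed]])
  j <- pmax(det[a[mixed]], det[b[mixed]])
  ok <- i != j
  counts <- .countMatrix(i[ok], j[ok], n)
  new("RandomsEstimate",
      method = "DW",
      rates = counts / stream@duration,
      duration = stream@duration,
      intermediate = list(counts = counts, delay = delay,
                          nMultiples = as.integer(w$nMultiples),
                          nSameDetector = as.integer(sum(!ok))))
}
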