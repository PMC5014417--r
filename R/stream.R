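## Singles list-mode stream generation: model-level (from a RateModel) and
## geometry-level (annihilation sampling), plus time jitter and paralysable
## dead time.

## Uniform arrival times with sub-nanosecond resolution. Base runif()
## values lie on a 2^-32 lattice, which over seconds-long acquisitions is
## coarse compared to a 10 ns coincidence window and visibly distorts the
## small-gap statistics; dithering each draw by a uniform offset of one
## lattice cell restores an exactly continuous uniform distribution.
.rtimes <- function(n, duration) {
  u <- (runif(n) + (runif(n) - 0.5) * 2^-31) %% 1
  u * duration
}

## canonical event ordering; ties in time are broken by detector then
## annihilation id so that equal seeds give bit-identical streams
.orderEvents <- function(ev) {
  ev[order(ev$time, ev$detector, ev$annihilationId), , drop = FALSE]
}

.newStream <- function(ev, duration, nDetectors, provenance = list()) {
  rownames(ev) <- NULL
  new("SinglesStream", events = ev, duration = as.numeric(duration),
      nDetectors = as.integer(nDetectors), provenance = provenance)
}

.emptyEvents <- function() {
  data.frame(time = numeric(), detector = integer(),
             annihilationId = integer(), photonIndex = integer())
}

#' Simulate a singles stream from a rate model
#'
#' Model-level simulation: uncorrelated singles on detector i arrive as a
#' homogeneous Poisson process of rate lambda_i; correlated pairs on LoR
#' (i, j) arrive as a Poisson process of rate rho_ij, each arrival emitting
#' two simultaneous singles (one on each detector) that share a fresh
#' annihilation id. The returned stream is the merged, time-sorted
#' superposition; the activity is constant over the acquisition. Every
#' event carries a unique ground-truth annihilation id (uncorrelated
#' singles each get their own), so streams from this generator are always
#' labeled.
#'
#' @param model a [RateModel-class].
#' @param duration acquisition time, s.
#' @param seed optional RNG seed.
#' @return a [SinglesStream-class].
#' @examples
#' rm <- rateModel(rep(1e3, 8), matrix(0, 8, 8))
#' st <- simulateModelStream(rm, 0.1, seed = 1)
#' @export
simulateModelStream <- function(model, duration, seed = NULL) {
  stopifnot(is(model, "RateModel"))
  if (duration <= 0) stop("duration must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- nDetectors(model)

  ## correlated pairs
  ut <- which(upper.tri(model@rho) & model@rho > 0, arr.ind = TRUE)
  pt <- numeric(0); pi_ <- integer(0); pj <- integer(0)
  if (nrow(ut)) {
    counts <- rpois(nrow(ut), model@rho[ut] * duration)
    tot <- sum(counts)
    if (tot) {
      pt <- .rtimes(tot, duration)
      pi_ <- rep(ut[, 1L], counts)
      pj <- rep(ut[, 2L], counts)
    }
  }
  nPairs <- length(pt)

  ## uncorrelated singles
  uc <- rpois(n, model@lambda * duration)
  nU <- sum(uc)
  uTime <- .rtimes(nU, duration)
  uDet <- rep(seq_len(n), uc)

  ev <- data.frame(
    time = c(pt, pt, uTime),
    detector = as.integer(c(pi_, pj, uDet)),
    annihilationId = as.integer(c(seq_len(nPairs), seq_len(nPairs),
                                  nPairs + seq_len(nU))),
    photonIndex = as.integer(c(rep(0L, nPairs), rep(1L, nPairs),
                               rep(0L, nU))))
  .newStream(.orderEvents(ev), duration, n,
             provenance = list(generator = "model", seed = seed))
}

#' Simulate a singles stream by annihilation sampling
#'
#' Geometry-level simulation: annihilation times arrive as a Poisson
#' process of rate `totalActivity(phantom)`; positions are sampled
#' proportionally to the activity concentration and each annihilation emits
#' a back-to-back photon pair in a uniform direction. Each photon reaching
#' the ring is detected independently with probability `efficiency`;
#' detected photons become singles carrying their annihilation's id.
#'
#' @param scanner a [ScannerGeometry-class].
#' @param phantom a [PhantomSpec-class] (must lie inside the bore).
#' @param duration acquisition time, s.
#' @param efficiency per-photon detection probability.
#' @param seed optional RNG seed.
#' @return a [SinglesStream-class].
#' @export
simulateAnnihilationStream <- function(scanner, phantom, duration,
                                       efficiency = 0.5, seed = NULL) {
  stopifnot(is(scanner, "ScannerGeometry"), is(phantom, "PhantomSpec"))
  if (duration <= 0) stop("duration must be positive")
  if (phantom@outsideFov)
    stop("annihilation-level simulation needs the phantom inside the FoV; ",
         "use deriveRateModel() + simulateModelStream() for outside sources")
  .checkInsideBore(scanner, phantom)
  if (!is.null(seed)) set.seed(seed)
  n <- nDetectors(scanner)
  nAnn <- rpois(1L, totalActivity(phantom) * duration)
  if (nAnn == 0L)
    return(.newStream(.emptyEvents(), duration, n,
                      provenance = list(generator = "annihilation",
                                        seed = seed)))
  tAnn <- .rtimes(nAnn, duration)
  pos <- .samplePositions(phantom, nAnn)
  phi <- runif(nAnn, 0, 2 * pi)
  det <- .tracePairs(pos, phi, scanner)
  d1 <- runif(nAnn) < efficiency
  d2 <- runif(nAnn) < efficiency
  ev <- data.frame(
    time = c(tAnn[d1], tAnn[d2]),
    detector = as.integer(c(det[d1, 1L], det[d2, 2L])),
    annihilationId = as.integer(c(which(d1), which(d2))),
    photonIndex = as.integer(c(rep(0L, sum(d1)), rep(1L, sum(d2)))))
  .newStream(.orderEvents(ev), duration, n,
             provenance = list(generator = "annihilation", seed = seed))
}

#' Apply Gaussian time jitter to a stream
#'
#' Each event time is perturbed by an independent zero-mean Gaussian. The
#' `fwhm` argument is the coincidence time resolution (FWHM of the time
#' difference of a correlated pair); since the two members are jittered
#' independently, the per-single standard deviation is
#' `fwhm / (2 * sqrt(2 * log(2))) / sqrt(2)`. The stream is re-sorted and
#' times are clamped into `[0, duration)`.
#'
#' @param stream a [SinglesStream-class].
#' @param fwhm coincidence time resolution FWHM, s (0 = no-op).
#' @param seed optional RNG seed.
#' @return a [SinglesStream-class].
#' @export
applyTimeJitter <- function(stream, fwhm, seed = NULL) {
  stopifnot(is(stream, "SinglesStream"), fwhm >= 0)
  if (fwhm == 0 || nrow(stream@events) == 0L) return(stream)
  if (!is.null(seed)) set.seed(seed)
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / sqrt(2)
  ev <- stream@events
  ev$time <- ev$time + rnorm(nrow(ev), 0, sigma)
  ev$time <- pmin(pmax(ev$time, 0), stream@duration * (1 - 1e-12))
  .newStream(.orderEvents(ev), stream@duration, stream@nDetectors,
             provenance = c(stream@provenance, list(jitterFwhm = fwhm)))
}

#' Apply paralysable dead time
#'
#' Paralysable semantics: every arriving event, recorded or not, extends
#' the dead window by `deadTime` from its own arrival; an event is recorded
#' iff no arrival occurred within the preceding `deadTime`. The default
#' scope is per-detector (each crystal read out individually); `"global"`
#' treats the whole scanner as one channel.
#'
#' @param stream a [SinglesStream-class].
#' @param deadTime dead-time constant, s (0 = no-op).
#' @param model dead-time model; only `"paralysable"` is implemented.
#' @param scope `"detector"` or `"global"`.
#' @return a [SinglesStream-class] containing the recorded events.
#' @export
applyDeadTime <- function(stream, deadTime, model = "paralysable",
                          scope = c("detector", "global")) {
  stopifnot(is(stream, "SinglesStream"), deadTime >= 0)
  model <- match.arg(model, "paralysable")
  scope <- match.arg(scope)
  if (deadTime == 0 || nrow(stream@events) == 0L) return(stream)
  ev <- stream@events
  if (scope == "global") {
    keep <- c(TRUE, diff(ev$time) > deadTime)
  } else {
    keep <- logical(nrow(ev))
    for (d in unique(ev$detector)) {
      idx <- which(ev$detector == d)
      keep[idx] <- c(TRUE, diff(ev$time[idx]) > deadTime)
    }
  }
  .newStream(ev[keep, , drop = FALSE], stream@duration, stream@nDetectors,
             provenance = c(stream@provenance,
                            list(deadTime = deadTime, deadTimeScope = scope)))
}
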