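## Accessor generics and methods. Slot access stays internal; user code goes
## through these.

#' Accessors for the core classes
#'
#' Small read-only accessors: number of detectors, coincidence window,
#' acquisition duration, event table, per-LoR tables and totals.
#'
#' @param object one of the package's S4 objects.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nDetectors", function(object) standardGeneric("nDetectors"))

#' @rdname accessors
#' @export
setMethod("nDetectors", "ScannerGeometry", function(object) object@nDetectors)

#' @rdname accessors
#' @export
setMethod("nDetectors", "RateModel", function(object) length(object@lambda))

#' @rdname accessors
#' @export
setMethod("nDetectors", "SinglesStream", function(object) object@nDetectors)

#' @rdname accessors
#' @export
setMethod("nDetectors", "PromptSet", function(object) nrow(object@counts))

#' @rdname accessors
#' @export
setMethod("nDetectors", "RandomsEstimate", function(object) nrow(object@rates))

#' @rdname accessors
#' @export
tcw <- function(object) object@tcw

#' @rdname accessors
#' @export
dwDelay <- function(object) object@dwDelay

#' @rdname accessors
#' @export
deadTime <- function(object) object@deadTime

#' @rdname accessors
#' @export
ringDiameter <- function(object) object@ringDiameter

#' @rdname accessors
#' @export
timeResolutionFwhm <- function(object) object@timeResolutionFwhm

#' @rdname accessors
#' @export
setGeneric("duration", function(object) standardGeneric("duration"))

#' @rdname accessors
#' @export
setMethod("duration", "SinglesStream", function(object) object@duration)

#' @rdname accessors
#' @export
setMethod("duration", "PromptSet", function(object) object@duration)

#' @rdname accessors
#' @export
setMethod("duration", "RandomsEstimate", function(object) object@duration)

#' @rdname accessors
#' @export
events <- function(object) {
  stopifnot(is(object, "SinglesStream"))
  object@events
}

#' @rdname accessors
#' @export
prompts <- function(object) {
  stopifnot(is(object, "PromptSet"))
  object@prompts
}

#' Is a stream ground-truth labeled?
#'
#' A stream is labeled when every event carries a non-negative annihilation
#' tag (streams produced by the package's simulators always are).
#'
#' @param object a [SinglesStream-class].
#' @return logical scalar.
#' @export
isLabeled <- function(object) {
  stopifnot(is(object, "SinglesStream"))
  nrow(object@events) == 0L || all(object@events$annihilationId >= 0L)
}

#' @rdname accessors
#' @export
promptCounts <- function(object) {
  stopifnot(is(object, "PromptSet"))
  object@counts
}

#' @rdname accessors
#' @export
trueCounts <- function(object) {
  stopifnot(is(object, "PromptSet"))
  if (!object@labeled) stop("PromptSet has not been classified")
  object@trues
}

#' @rdname accessors
#' @export
randomCounts <- function(object) {
  stopifnot(is(object, "PromptSet"))
  if (!object@labeled) stop("PromptSet has not been classified")
  object@randoms
}

#' @rdname accessors
#' @export
nMultiplesDiscarded <- function(object) {
  stopifnot(is(object, "PromptSet"))
  object@nMultiples
}

#' @rdname accessors
#' @export
estimateMethod <- function(object) {
  stopifnot(is(object, "RandomsEstimate"))
  object@method
}

#' @rdname accessors
#' @export
lorRates <- function(object) {
  stopifnot(is(object, "RandomsEstimate"))
  object@rates
}

#' @rdname accessors
#' @export
spDiagnostics <- function(object) {
  stopifnot(is(object, "RandomsEstimate"))
  object@intermediate
}

#' @rdname accessors
#' @export
uncorrelatedRates <- function(object) {
  stopifnot(is(object, "RateModel"))
  object@lambda
}

#' @rdname accessors
#' @export
correlatedRates <- function(object) {
  stopifnot(is(object, "RateModel"))
  object@rho
}

#' Rate-model totals
#'
#' Total uncorrelated rate lambda, total correlated-pair singles rate rho
#' (counting both members of every pair: `rho = 2 * sum(rho_ij)` singles/s
#' would double-count, so here `rho` is the total pair-singles rate
#' `sum_i rho_i = 2 * sum_{i<j} rho_ij`), and the window-occupying rate
#' `Lambda = lambda + rho / 2`.
#'
#' @param object a [RateModel-class].
#' @return named numeric vector with `lambda`, `rho`, `Lambda` (all
#'   counts/s) and `S` (`lambda + rho`, the expected total singles rate).
#' @export
rateTotals <- function(object) {
  stopifnot(is(object, "RateModel"))
  lam <- sum(object@lambda)
  rho <- 2 * sum(object@rho)            # singles/s from correlated pairs
  c(lambda = lam, rho = rho, Lambda = lam + rho / 2, S = lam + rho)
}

#' @rdname accessors
#' @export
imageValues <- function(object) {
  stopifnot(is(object, "ReconImage"))
  object@values
}

#' @rdname accessors
#' @export
imageGrid <- function(object) {
  stopifnot(is(object, "ReconImage"))
  object@grid
}

#' @rdname accessors
#' @export
imageHistory <- function(object) {
  stopifnot(is(object, "ReconImage"))
  object@history
}

#' @rdname accessors
#' @export
pixelSize <- function(object) {
  stopifnot(is(object, "ReconGrid"))
  object@fov / object@n
}

#' @rdname accessors
#' @export
totalActivity <- function(object) {
  stopifnot(is(object, "PhantomSpec"))
  object@totalActivity
}

#' @rdname accessors
#' @export
primitives <- function(object) {
  stopifnot(is(object, "PhantomSpec"))
  object@primitives
}
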