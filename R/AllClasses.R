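#' @import methods
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rpois runif rnorm rbinom var uniroot
#' @importFrom utils head tail
#' @useDynLib randcoinc, .registration = TRUE
NULL

#' ScannerGeometry: a single 2D detector ring
#'
#' Describes the toy cylindrical PET scanner reduced to one transaxial ring
#' of point-like detector centres placed uniformly on a circle. All times are
#' stored in seconds and all lengths in millimetres; the [makeRing()]
#' constructor accepts the timing parameters in nanoseconds for convenience.
#'
#' @slot nDetectors integer, number of detectors on the ring (>= 3).
#' @slot ringDiameter numeric, inner ring diameter in mm.
#' @slot timeResolutionFwhm numeric, coincidence time resolution FWHM in s.
#' @slot tcw numeric, time coincidence window tau in s.
#' @slot dwDelay numeric, delayed-window offset in s (>> time resolution).
#' @slot deadTime numeric, paralysable dead-time constant in s (0 disables).
#'
#' @seealso [makeRing()]
#' @export
setClass("ScannerGeometry",
  representation(
    nDetectors = "integer",
    ringDiameter = "numeric",
    timeResolutionFwhm = "numeric",
    tcw = "numeric",
    dwDelay = "numeric",
    deadTime = "numeric"
  )
)

setValidity("ScannerGeometry", function(object) {
  msg <- character()
  if (length(object@nDetectors) != 1L || object@nDetectors < 3L)
    msg <- c(msg, "nDetectors must be a single integer >= 3")
  if (object@ringDiameter <= 0)
    msg <- c(msg, "ringDiameter must be positive")
  if (object@tcw <= 0)
    msg <- c(msg, "tcw must be positive")
  if (object@timeResolutionFwhm < 0)
    msg <- c(msg, "timeResolutionFwhm must be non-negative")
  if (object@dwDelay <= object@tcw)
    msg <- c(msg, "dwDelay must exceed the coincidence window")
  if (object@deadTime < 0)
    msg <- c(msg, "deadTime must be non-negative")
  if (length(msg)) msg else TRUE
})

#' PhantomSpec: 2D activity distribution
#'
#' A phantom is an ordered list of circular primitives; where primitives
#' overlap, the last one listed wins (so inserts carve their parent disc).
#' A `point` primitive has radius 0 and concentrates its activity at its
#' centre. `outsideFov = TRUE` marks a source placed axially outside the
#' ring: its photons can reach the detectors only one at a time, so it
#' produces uncorrelated singles exclusively (the correlated-pair rates are
#' forced to zero by [deriveRateModel()]).
#'
#' @slot primitives data.frame with columns `shape` ("disc" or "point"),
#'   `x`, `y` (centre, mm), `radius` (mm), `concentration` (relative
#'   activity concentration, Bq/mm^2 up to normalisation).
#' @slot totalActivity numeric, total activity in Bq; the primitive
#'   concentrations are rescaled so their integral equals this value.
#' @slot outsideFov logical flag, see above.
#'
#' @seealso [discPhantom()], [pointPhantom()], [iqPhantom()],
#'   [outsideFovPhantom()]
#' @export
setClass("PhantomSpec",
  representation(
    primitives = "data.frame",
    totalActivity = "numeric",
    outsideFov = "logical"
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  pr <- object@primitives
  need <- c("shape", "x", "y", "radius", "concentration")
  if (!all(need %in% names(pr)))
    msg <- c(msg, sprintf("primitives must have columns %s",
                          paste(need, collapse = ", ")))
  else {
    if (any(pr$radius < 0)) msg <- c(msg, "primitive radii must be >= 0")
    if (any(pr$concentration < 0))
      msg <- c(msg, "concentrations must be >= 0")
    if (!all(pr$shape %in% c("disc", "point")))
      msg <- c(msg, "shape must be 'disc' or 'point'")
  }
  if (object@totalActivity < 0) msg <- c(msg, "totalActivity must be >= 0")
  if (length(msg)) msg else TRUE
})

#' RateModel: Poisson source rates behind a singles stream
#'
#' The statistical detection model: each detector i receives uncorrelated
#' singles as a homogeneous Poisson process of rate lambda_i, and each
#' detector pair (i, j) receives correlated singles pairs as a Poisson
#' process of rate rho_ij. Derived totals are lambda = sum(lambda_i),
#' rho = sum_ij(rho_ij), and the window-occupying rate
#' Lambda = lambda + rho / 2.
#'
#' @slot lambda numeric vector of per-detector uncorrelated-singles rates
#'   (counts/s).
#' @slot rho numeric matrix of per-LoR correlated-pair rates (pairs/s);
#'   upper-triangular storage, `rho[i, j]` with i < j.
#'
#' @seealso [rateModel()], [deriveRateModel()], [simulateModelStream()]
#' @export
setClass("RateModel",
  representation(lambda = "numeric", rho = "matrix")
)

setValidity("RateModel", function(object) {
  n <- length(object@lambda)
  msg <- character()
  if (any(object@lambda < 0)) msg <- c(msg, "lambda rates must be >= 0")
  if (!all(dim(object@rho) == c(n, n)))
    msg <- c(msg, "rho must be an n x n matrix matching lambda")
  else {
    if (any(object@rho < 0)) msg <- c(msg, "rho rates must be >= 0")
    if (any(diag(object@rho) != 0)) msg <- c(msg, "rho diagonal must be 0")
    if (any(object@rho[lower.tri(object@rho)] != 0))
      msg <- c(msg, "rho must be stored in the upper triangle only")
  }
  if (length(msg)) msg else TRUE
})

#' SinglesStream: time-ordered singles list-mode events
#'
#' @slot events data.frame with columns `time` (s), `detector` (1-based
#'   index), `annihilationId` (integer ground-truth tag, -1 when unlabeled),
#'   `photonIndex` (0 or 1 within its annihilation).
#' @slot duration numeric, acquisition time in seconds.
#' @slot nDetectors integer, ring size the detector indices refer to.
#' @slot provenance list of free-form metadata (seed, generator, rates).
#'
#' @seealso [simulateModelStream()], [simulateAnnihilationStream()]
#' @export
setClass("SinglesStream",
  representation(
    events = "data.frame",
    duration = "numeric",
    nDetectors = "integer",
    provenance = "list"
  )
)

setValidity("SinglesStream", function(object) {
  ev <- object@events
  msg <- character()
  need <- c("time", "detector", "annihilationId", "photonIndex")
  if (!all(need %in% names(ev)))
    return(sprintf("events must have columns %s", paste(need, collapse = ", ")))
  if (object@duration <= 0) msg <- c(msg, "duration must be positive")
  if (nrow(ev)) {
    if (is.unsorted(ev$time)) msg <- c(msg, "events must be time-sorted")
    if (any(ev$time < 0) || any(ev$time >= object@duration))
      msg <- c(msg, "event times must lie in [0, duration)")
    if (any(ev$detector < 1L) || any(ev$detector > object@nDetectors))
      msg <- c(msg, "detector indices out of range")
  }
  if (length(msg)) msg else TRUE
})

#' PromptSet: sorted prompt coincidences
#'
#' Output of the single-window sorter: one row per prompt, the per-LoR
#' count table, and the bookkeeping counts for discarded events. When the
#' input stream carried ground-truth annihilation tags,
#' [classifyPrompts()] fills the `label` column ("true" / "random") and the
#' trues/randoms count tables.
#'
#' @slot prompts data.frame with columns `i`, `j` (canonical i < j),
#'   `windowOpen` (s), `id1`, `id2` (annihilation tags of the two singles,
#'   -1 when unlabeled), `label` ("true", "random" or "unlabeled").
#' @slot counts integer matrix, upper-triangular per-LoR prompt counts.
#' @slot trues,randoms integer matrices, per-LoR counts after
#'   classification (all zero before).
#' @slot nMultiples integer, multiple-coincidence windows discarded.
#' @slot nSameDetector integer, prompts discarded because both singles hit
#'   the same detector (no valid LoR).
#' @slot duration numeric, s.
#' @slot tcw numeric, the window used, s.
#' @slot labeled logical, whether classification has been performed.
#'
#' @seealso [swSort()], [classifyPrompts()]
#' @export
setClass("PromptSet",
  representation(
    prompts = "data.frame",
    counts = "matrix",
    trues = "matrix",
    randoms = "matrix",
    nMultiples = "integer",
    nSameDetector = "integer",
    duration = "numeric",
    tcw = "numeric",
    labeled = "logical"
  )
)

setValidity("PromptSet", function(object) {
  msg <- character()
  if (sum(object@counts) != nrow(object@prompts))
    msg <- c(msg, "counts table must sum to the number of prompts")
  if (object@labeled &&
      any(object@trues + object@randoms != object@counts))
    msg <- c(msg, "trues + randoms must equal prompt counts")
  if (length(msg)) msg else TRUE
})

#' RandomsEstimate: per-LoR randoms rates for one method
#'
#' @slot method character, one of "SR", "DW", "SP", "ideal" or "model".
#' @slot rates numeric matrix, upper-triangular per-LoR randoms rates
#'   (counts/s), `rates[i, j]` with i < j.
#' @slot duration numeric, s (NA for the closed-form model oracle).
#' @slot intermediate list; for SP it carries `lambdaHat`, `LambdaHat`,
#'   `tauEff`, `sEff` (effective singles rates), `nClamped` (negative
#'   effective rates floored at zero) and the solver diagnostics.
#'
#' @seealso [estimateSR()], [estimateSP()], [dwSort()], [estimateIdeal()],
#'   [modelRandomsRate()]
#' @export
setClass("RandomsEstimate",
  representation(
    method = "character",
    rates = "matrix",
    duration = "numeric",
    intermediate = "list"
  )
)

setValidity("RandomsEstimate", function(object) {
  msg <- character()
  if (!object@method %in% c("SR", "DW", "SP", "ideal", "model"))
    msg <- c(msg, "unknown method tag")
  if (any(object@rates < 0)) msg <- c(msg, "randoms rates must be >= 0")
  if (length(msg)) msg else TRUE
})

#' ReconGrid: square pixel grid covering the field of view
#'
#' @slot n integer, pixels per side.
#' @slot fov numeric, grid width in mm (the grid is centred on the scanner
#'   axis).
#' @export
setClass("ReconGrid", representation(n = "integer", fov = "numeric"))

setValidity("ReconGrid", function(object) {
  if (object@n < 2L || object@fov <= 0)
    "grid needs n >= 2 pixels and a positive fov" else TRUE
})

#' ReconImage: ML-EM reconstruction result
#'
#' @slot values numeric matrix (n x n), non-negative voxel intensities;
#'   `values[ix, iy]` with ix along +x and iy along +y.
#' @slot grid the [ReconGrid-class] the image lives on.
#' @slot iterations integer, ML-EM iterations performed.
#' @slot history list of value matrices at requested intermediate
#'   iterations (named by iteration number).
#' @seealso [mlem()]
#' @export
setClass("ReconImage",
  representation(
    values = "matrix",
    grid = "ReconGrid",
    iterations = "integer",
    history = "list"
  )
)

setValidity("ReconImage", function(object) {
  if (any(object@values < 0)) "image values must be non-negative" else TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "ScannerGeometry", function(object) {
  cat(sprintf(
    "ScannerGeometry: %d detectors on a %.1f mm ring\n  tcw %.3g ns, dw delay %.3g ns, time resolution %.3g ns FWHM, dead time %.3g ns\n",
    object@nDetectors, object@ringDiameter, object@tcw * 1e9,
    object@dwDelay * 1e9, object@timeResolutionFwhm * 1e9,
    object@deadTime * 1e9))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %d primitive(s), total activity %.4g Bq%s\n",
              nrow(object@primitives), object@totalActivity,
              if (object@outsideFov) " (outside FoV)" else ""))
  print(object@primitives)
})

setMethod("show", "RateModel", function(object) {
  cat(sprintf(
    "RateModel: %d detectors\n  lambda = %.6g cps, rho = %.6g pairs/s, Lambda = %.6g cps\n",
    length(object@lambda), sum(object@lambda), sum(object@rho),
    sum(object@lambda) + sum(object@rho) / 2))
})

setMethod("show", "SinglesStream", function(object) {
  cat(sprintf(
    "SinglesStream: %d events over %.4g s on %d detectors (%s)\n",
    nrow(object@events), object@duration, object@nDetectors,
    if (isLabeled(object)) "ground-truth labeled" else "unlabeled"))
})

setMethod("show", "PromptSet", function(object) {
  cat(sprintf(
    "PromptSet: %d prompts over %.4g s (tcw %.3g ns); %d multiples, %d same-detector discarded%s\n",
    nrow(object@prompts), object@duration, object@tcw * 1e9,
    object@nMultiples, object@nSameDetector,
    if (object@labeled)
      sprintf("; %d trues / %d randoms", sum(object@trues),
              sum(object@randoms))
    else ""))
})

setMethod("show", "RandomsEstimate", function(object) {
  cat(sprintf("RandomsEstimate (%s): total %.6g cps over %d detectors\n",
              object@method, sum(object@rates), nrow(object@rates)))
})

setMethod("show", "ReconImage", function(object) {
  cat(sprintf(
    "ReconImage: %d x %d pixels (%.3g mm), %d ML-EM iterations, total intensity %.6g\n",
    object@grid@n, object@grid@n, pixelSize(object@grid),
    object@iterations, sum(object@values)))
})
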