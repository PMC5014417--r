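## Scanner-level performance metrics: totals, Fano factors, randoms
## fraction, NECR and NECR curves versus activity.

#' Total randoms rate of an estimate
#'
#' Sum of the per-LoR rates over unique LoRs (i < j), the scanner-level
#' extensive magnitude used to compare methods.
#'
#' @param estimate a [RandomsEstimate-class].
#' @return scalar rate, counts/s.
#' @export
totalRate <- function(estimate) {
  stopifnot(is(estimate, "RandomsEstimate"))
  sum(estimate@rates)
}

#' Per-LoR rates as a vector over linear LoR indices
#'
#' @param estimate a [RandomsEstimate-class].
#' @return numeric vector of length `nLors(n)` ordered by [lorIndex()].
#' @export
lorRateVector <- function(estimate) {
  stopifnot(is(estimate, "RandomsEstimate"))
  n <- nrow(estimate@rates)
  estimate@rates[lorPair(seq_len(nLors(n)), n)]
}

#' Fano factor
#'
#' Ratio of the unbiased sample variance to the sample mean of replicate
#' counts; 1 for a Poisson counting process, 0 for a deterministic one.
#'
#' @param samples numeric vector of replicate counts (length >= 2, positive
#'   mean).
#' @return scalar Fano factor.
#' @export
fanoFactor <- function(samples) {
  if (length(samples) < 2L) stop("need at least 2 replicates")
  m <- mean(samples)
  if (m <= 0) stop("Fano factor undefined for non-positive mean")
  var(samples) / m
}

#' Randoms fraction from ground truth
#'
#' @param promptSet a classified [PromptSet-class].
#' @return randoms / prompts (in `[0, 1]`).
#' @export
randomsFraction <- function(promptSet) {
  stopifnot(is(promptSet, "PromptSet"))
  if (!promptSet@labeled) stop("randoms fraction needs classified prompts")
  nP <- nrow(promptSet@prompts)
  if (nP == 0L) stop("randoms fraction undefined without prompts")
  sum(promptSet@randoms) / nP
}

#' Noise-equivalent count rate
#'
#' `NECR = (P - R)^2 / (P - R + (1 + F) * Rpht)` where `P` is the scanner
#' prompts rate (coincidences/s, *not* the doubled rate of the pile-up
#' equation), `R` the estimated total randoms rate, `Rpht` the estimated
#' randoms rate restricted to LoRs passing through the phantom, and `F` the
#' method's Fano factor. If the method estimates more randoms than there
#' are prompts the estimated trues are negative and NECR is reported as 0
#' with a warning.
#'
#' @param promptsRate scanner prompts rate, counts/s.
#' @param randomsTotal estimated total randoms rate, counts/s.
#' @param randomsPhantom estimated randoms rate on phantom-crossing LoRs,
#'   counts/s (must not exceed `randomsTotal`).
#' @param fano the method's Fano factor.
#' @return scalar NECR, counts/s.
#' @examples
#' necr(100, 50, 50, 0)   # 2500 / 100 = 25
#' @export
necr <- function(promptsRate, randomsTotal, randomsPhantom, fano) {
  stopifnot(randomsPhantom <= randomsTotal + 1e-9)
  trues <- promptsRate - randomsTotal
  if (trues < 0) {
    warning("estimated randoms exceed prompts; NECR reported as 0")
    return(0)
  }
  denom <- trues + (1 + fano) * randomsPhantom
  if (denom <= 0) return(0)
  trues^2 / denom
}

#' Deterministic child seeds from a master seed
#'
#' Counter-based splitting so that adding replicates never perturbs
#' existing ones; results stay below 2^31.
#'
#' @param master master seed (integer).
#' @param index replicate counter (integer >= 1).
#' @return integer seed.
#' @export
childSeed <- function(master, index) {
  as.integer((as.numeric(master) %% 65521) * 31019 +
               (as.numeric(index) %% 65521) * 613 + 1)
}

#' Run one replicate of the full estimation chain
#'
#' Simulates a model-level stream, sorts and classifies prompts, and
#' computes all four randoms estimates plus the scanner prompts rate.
#' Workhorse for replicate ensembles and NECR curves.
#'
#' @param model a [RateModel-class].
#' @param scanner a [ScannerGeometry-class] (supplies tcw and DW delay).
#' @param duration acquisition time, s.
#' @param seed RNG seed for this replicate.
#' @param methods subset of `c("SR", "DW", "SP", "ideal")`.
#' @return list with `estimates` (named list of [RandomsEstimate-class]),
#'   `promptsRate`, `promptSet`, `singles`.
#' @export
runReplicate <- function(model, scanner, duration, seed,
                         methods = c("SR", "DW", "SP", "ideal")) {
  st <- simulateModelStream(model, duration, seed = seed)
  ps <- classifyPrompts(swSort(st, tcw(scanner)))
  si <- singlesRates(st)
  est <- list()
  if ("SR" %in% methods)
    est$SR <- estimateSR(si, tcw(scanner), duration)
  if ("SP" %in% methods)
    est$SP <- estimateSP(si, ps, tcw(scanner))
  if ("DW" %in% methods)
    est$DW <- dwSort(st, tcw(scanner), dwDelay(scanner))
  if ("ideal" %in% methods)
    est$ideal <- estimateIdeal(ps)
  list(estimates = est, promptsRate = nrow(prompts(ps)) / duration,
       promptSet = ps, singles = si)
}

#' NECR curve versus activity
#'
#' For each activity: rescale the base rate model, simulate `nReplicates`
#' labeled streams, estimate randoms with each method, and assemble NECR
#' points. The Fano factor of each method is computed across the
#' replicates from the total estimated randoms counts.
#'
#' @param scanner a [ScannerGeometry-class].
#' @param model base [RateModel-class] (rates at its own activity
#'   `sum(rateTotals(model)[["S"]])`; rescaled linearly per activity).
#' @param modelActivity the source activity (Bq) the base model
#'   corresponds to.
#' @param activities ascending vector of activities, Bq.
#' @param phantomMask logical vector over linear LoR indices (from
#'   [lorThroughPhantom()]) restricting the NECR randoms term.
#' @param duration per-replicate acquisition time, s.
#' @param nReplicates replicates per activity (>= 2).
#' @param seed master seed.
#' @param methods estimation methods to include.
#' @return data.frame with one row per (activity, method): columns
#'   `activity`, `method`, `promptsRate`, `randomsTotal`, `randomsPhantom`,
#'   `overIdeal` (mean R/R0), `fano`, `necr`.
#' @export
necrCurve <- function(scanner, model, modelActivity, activities,
                      phantomMask, duration = 1, nReplicates = 10,
                      seed = 1, methods = c("SR", "DW", "SP", "ideal")) {
  stopifnot(!is.unsorted(activities), nReplicates >= 2L)
  methods <- match.arg(methods, several.ok = TRUE)
  out <- list()
  rep0 <- 0L
  for (act in activities) {
    m <- scaleRateModel(model, act / modelActivity)
    tot <- lapply(methods, function(x) numeric(nReplicates))
    names(tot) <- methods
    pht <- tot
    pRate <- numeric(nReplicates)
    r0 <- numeric(nReplicates)
    for (r in seq_len(nReplicates)) {
      rep0 <- rep0 + 1L
      one <- runReplicate(m, scanner, duration, childSeed(seed, rep0),
                          methods = union(methods, "ideal"))
      pRate[r] <- one$promptsRate
      r0[r] <- totalRate(one$estimates$ideal)
      for (mm in methods) {
        v <- lorRateVector(one$estimates[[mm]])
        tot[[mm]][r] <- sum(v)
        pht[[mm]][r] <- sum(v[phantomMask])
      }
    }
    for (mm in methods) {
      counts <- tot[[mm]] * duration
      f <- if (mean(counts) > 0) fanoFactor(counts) else 0
      out[[length(out) + 1L]] <- data.frame(
        activity = act, method = mm,
        promptsRate = mean(pRate),
        randomsTotal = mean(tot[[mm]]),
        randomsPhantom = mean(pht[[mm]]),
        overIdeal = if (mean(r0) > 0) mean(tot[[mm]]) / mean(r0) else NA_real_,
        fano = f,
        necr = necr(mean(pRate), mean(tot[[mm]]), mean(pht[[mm]]), f))
    }
  }
  do.call(rbind, out)
}
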