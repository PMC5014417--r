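## Randoms-rate estimators: singles-rate (SR), singles-prompts (SP) with its
## pile-up solver and effective-window reformulation, the ground-truth ideal
## estimate, and the closed-form model oracle.

#' Per-detector singles rates
#'
#' `S_i` is the raw event count on detector i divided by the acquisition
#' time; no coincidence extraction is involved in counting singles.
#'
#' @param stream a [SinglesStream-class].
#' @return numeric vector of per-detector rates (counts/s); the scanner
#'   total is `sum()` of it.
#' @export
singlesRates <- function(stream) {
  stopifnot(is(stream, "SinglesStream"))
  tabulate(stream@events$detector, nbins = stream@nDetectors) /
    stream@duration
}

## upper-triangular outer product helper: 2 * tau * s_i * s_j for i < j
.pairRates <- function(s, tau) {
  m <- 2 * tau * outer(s, s)
  m[lower.tri(m, diag = TRUE)] <- 0
  m
}

#' Singles-rate (SR) randoms estimate
#'
#' The textbook estimate `R_ij = 2 * tcw * S_i * S_j`, valid when the
#' singles rates dominate the trues rates and pile-up is negligible.
#'
#' @param singles per-detector singles rates (from [singlesRates()]),
#'   counts/s.
#' @param tcw coincidence window, s.
#' @param duration optional acquisition time, s (recorded for count
#'   conversion downstream).
#' @return a [RandomsEstimate-class] with method `"SR"`.
#' @examples
#' est <- estimateSR(rep(1e5, 4), 10e-9)
#' lorRates(est)[1, 2]    # 2 * 10e-9 * 1e5 * 1e5 = 200 cps
#' @export
estimateSR <- function(singles, tcw, duration = NA_real_) {
  stopifnot(all(singles >= 0), tcw > 0)
  new("RandomsEstimate", method = "SR",
      rates = .pairRates(singles, tcw),
      duration = as.numeric(duration),
      intermediate = list())
}

#' Solve for the total uncorrelated-singles rate
#'
#' Finds the physical root lambda of
#' `2 * tcw * lambda^2 - lambda + S - P * exp((lambda + S) * tcw) = 0`,
#' where `S` is the scanner singles rate and `P` is *twice* the scanner
#' prompts rate. The root is bracketed on a grid over
#' `[0, S * (1 + 8 * tcw * S)]` — the model bound is `lambda <= S`, but
#' under sampling noise (or with no prompts at all) the root can exceed
#' `S` by a factor of order `1 + 2 * tcw * S`, and clamping it at `S`
#' would bias the estimator — and refined by Newton iteration to relative
#' tolerance 1e-12. If several roots exist the one continuous with the
#' zero-window limit `lambda = S - P` is returned.
#'
#' @param S total singles rate, counts/s.
#' @param doubledPromptsRate `P`, twice the scanner prompts rate, counts/s.
#' @param tcw coincidence window, s (0 gives the degenerate linear root).
#' @return lambda, counts/s.
#' @examples
#' solveLambda(1000, 100, 0)    # 900
#' @export
solveLambda <- function(S, doubledPromptsRate, tcw) {
  P <- doubledPromptsRate
  stopifnot(S >= 0, P >= 0, tcw >= 0)
  if (tcw == 0) {
    if (P > S) stop("no root in [0, S]: prompts rate exceeds singles rate")
    return(S - P)
  }
  if (S == 0) {
    if (P > 0) stop("no root in [0, S]: prompts without singles")
    return(0)
  }
  f <- function(l) 2 * tcw * l^2 - l + S - P * exp((l + S) * tcw)
  upper <- S * (1 + 8 * tcw * S)
  grid <- seq(0, upper, length.out = 257L)
  fg <- f(grid)
  sgn <- sign(fg)
  roots <- grid[fg == 0]
  cross <- which(sgn[-1L] * sgn[-length(sgn)] < 0)
  for (k in cross) {
    r <- uniroot(f, c(grid[k], grid[k + 1L]), tol = S * 1e-13)$root
    roots <- c(roots, r)
  }
  if (!length(roots))
    stop(sprintf(
      "no physical root of the pile-up equation (S = %g, P = %g, f(0) = %g, f(upper) = %g)",
      S, P, fg[1L], fg[length(fg)]))
  lambda <- roots[which.min(abs(roots - (S - P)))]
  ## Newton polish
  fp <- function(l) 4 * tcw * l - 1 - P * tcw * exp((l + S) * tcw)
  for (it in seq_len(50L)) {
    step <- f(lambda) / fp(lambda)
    if (!is.finite(step)) break
    lambda <- lambda - step
    if (abs(step) <= 1e-12 * max(abs(lambda), 1)) break
  }
  min(max(lambda, 0), upper)
}

#' Effective coincidence window and effective singles rates
#'
#' The SP estimator can be written in the same form as SR with an
#' effective window and effective singles rates:
#' `tauEff = tcw * exp(-tcw * (lambda + S)) / (1 - 2 * tcw * lambda)^2`,
#' `sEff_k = S_k - P_k * exp(tcw * (lambda + S))`.
#'
#' @param lambda total uncorrelated-singles rate, counts/s (from
#'   [solveLambda()]).
#' @param S total singles rate, counts/s.
#' @param singles per-detector singles rates `S_k`, counts/s.
#' @param promptRatesPerDetector per-detector prompts rates
#'   `P_k = sum_j P_kj`, counts/s.
#' @param tcw coincidence window, s.
#' @return list with `tauEff` (s) and `sEff` (counts/s, may be negative
#'   under sampling noise; [estimateSP()] clamps them).
#' @export
effectiveParams <- function(lambda, S, singles, promptRatesPerDetector,
                            tcw) {
  stopifnot(tcw > 0)
  denom <- 1 - 2 * tcw * lambda
  if (abs(denom) < 1e-12)
    stop("singular configuration: 2 * tcw * lambda = 1")
  g <- exp(tcw * (lambda + S))
  list(tauEff = tcw / g / denom^2,
       sEff = singles - promptRatesPerDetector * g)
}

#' Singles-prompts (SP) randoms estimate
#'
#' Combines the per-detector singles rates with the sorter's per-detector
#' prompts rates to estimate the uncorrelated-singles rates and the
#' pile-up attenuation, then forms
#' `R_ij = 2 * tauEff * sEff_i * sEff_j`. Negative effective singles rates
#' (possible under sampling noise) are clamped to zero and counted in the
#' diagnostics. The scanner prompts rate entering the pile-up equation is
#' doubled internally, following the convention that `P = sum_i P_i`
#' counts every prompt at both of its detectors.
#'
#' @param singles per-detector singles rates, counts/s.
#' @param promptSet the [PromptSet-class] from [swSort()] (multiples are
#'   excluded from the prompts rate by construction: they never become
#'   prompts).
#' @param tcw coincidence window, s.
#' @return a [RandomsEstimate-class] with method `"SP"`; solver and
#'   effective-parameter diagnostics are in [spDiagnostics()].
#' @export
estimateSP <- function(singles, promptSet, tcw = promptSet@tcw) {
  stopifnot(is(promptSet, "PromptSet"), length(singles) ==
              nrow(promptSet@counts))
  S <- sum(singles)
  cnt <- promptSet@counts
  perDet <- (rowSums(cnt) + colSums(cnt)) / promptSet@duration
  P <- sum(perDet)                     # twice the prompts rate
  lambda <- solveLambda(S, P, tcw)
  ep <- effectiveParams(lambda, S, singles, perDet, tcw)
  nClamped <- sum(ep$sEff < 0)
  sEff <- pmax(ep$sEff, 0)
  new("RandomsEstimate", method = "SP",
      rates = .pairRates(sEff, ep$tauEff),   # 2 tauEff sEff_i sEff_j, i < j
      duration = promptSet@duration,
      intermediate = list(
        lambdaHat = lambda, LambdaHat = (S + lambda) / 2,
        tauEff = ep$tauEff, sEff = sEff, nClamped = nClamped,
        S = S, doubledPromptsRate = P))
}

## direct (non-factorised) form of the SP formula, kept as an independent
## arithmetic path for round-off cross-checks
.spRatesDirect <- function(singles, promptRatesPerDetector, lambda, S,
                           tcw) {
  g <- exp((lambda + S) * tcw)
  pref <- 2 * tcw * exp(-(lambda + S) * tcw) / (1 - 2 * lambda * tcw)^2
  eff <- singles - promptRatesPerDetector * g
  m <- pref * outer(eff, eff)
  m[lower.tri(m, diag = TRUE)] <- 0
  m
}

#' Ideal (ground-truth) randoms estimate
#'
#' The per-LoR rate of prompts labeled random by [classifyPrompts()]; only
#' available on simulated, labeled data. Serves as the reference `R^0`.
#'
#' @param promptSet a classified [PromptSet-class].
#' @return a [RandomsEstimate-class] with method `"ideal"`; the integer
#'   random counts are kept in `spDiagnostics(x)$counts`.
#' @export
estimateIdeal <- function(promptSet) {
  stopifnot(is(promptSet, "PromptSet"))
  if (!promptSet@labeled)
    stop("ideal estimate needs a classified PromptSet")
  new("RandomsEstimate", method = "ideal",
      rates = promptSet@randoms / promptSet@duration,
      duration = promptSet@duration,
      intermediate = list(counts = promptSet@randoms))
}

#' Closed-form randoms rate of a rate model
#'
#' The model prediction for the rate of randoms made of uncorrelated
#' singles sorted by a single-window sorter:
#' `R_ij = 2 * tcw * lambda_i * lambda_j * exp(-2 * Lambda * tcw)`, with
#' `Lambda` the total window-occupying rate. Used as the analytic oracle
#' for the simulation-based estimates.
#'
#' @param model a [RateModel-class].
#' @param tcw coincidence window, s.
#' @return a [RandomsEstimate-class] with method `"model"`.
#' @export
modelRandomsRate <- function(model, tcw) {
  stopifnot(is(model, "RateModel"), tcw > 0)
  tot <- rateTotals(model)
  att <- exp(-2 * tot[["Lambda"]] * tcw)
  new("RandomsEstimate", method = "model",
      rates = .pairRates(model@lambda, tcw) * att,
      duration = NA_real_,
      intermediate = list(Lambda = tot[["Lambda"]]))
}

#' Model prediction of singles and prompts rates
#'
#' Forward model used to cross-check the SP solver and the effective-rate
#' identities: per LoR,
#' `P_ij = (rho_ij + 2 tcw lambda_i lambda_j) exp(-2 Lambda tcw)`, and per
#' detector `S_i = rho_i + lambda_i`,
#' `P_i = (rho_i + 2 tcw lambda lambda_i) exp(-(S + lambda) tcw)` — the
#' per-detector and scanner totals follow the model's convention of
#' approximating the pair sum `sum_j lambda_i lambda_j` by
#' `lambda_i * lambda` (all pairs), so
#' `P = (rho + 2 tcw lambda^2) exp(-2 Lambda tcw)` with `P` doubled
#' (counting each prompt at both detectors). Feeding `S` and `P` to
#' [solveLambda()] recovers `lambda` exactly, and [effectiveParams()]
#' recovers the `lambda_i`.
#'
#' @param model a [RateModel-class].
#' @param tcw coincidence window, s.
#' @return list with `Si`, `S`, `Pij` (upper-triangular matrix), `Pi`,
#'   `doubledPromptsRate`.
#' @export
modelForwardRates <- function(model, tcw) {
  stopifnot(is(model, "RateModel"), tcw >= 0)
  tot <- rateTotals(model)
  att <- exp(-2 * tot[["Lambda"]] * tcw)   # == exp(-(S + lambda) tcw)
  rhoFull <- model@rho + t(model@rho)
  rhoI <- rowSums(rhoFull)
  Si <- rhoI + model@lambda
  ## rho and 2 tau li lj both live on the upper triangle, i < j
  Pij <- (model@rho + .pairRates(model@lambda, tcw)) * att
  lam <- tot[["lambda"]]
  Pi <- (rhoI + 2 * tcw * lam * model@lambda) * att
  list(Si = Si, S = sum(Si), Pij = Pij, Pi = Pi,
       doubledPromptsRate = (tot[["rho"]] + 2 * tcw * lam^2) * att)
}
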