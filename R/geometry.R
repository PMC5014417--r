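## Ring geometry, LoR indexing, phantoms and the Monte-Carlo rate model.

#' Construct the toy scanner ring
#'
#' Places `nDetectors` detector centres uniformly on a circle of diameter
#' `ringDiameter`. The timing parameters follow the usual convention that
#' the coincidence window is twice the coincidence time resolution (FWHM).
#' Times are taken in nanoseconds here and stored in seconds.
#'
#' @param nDetectors integer >= 3; detectors on the ring.
#' @param ringDiameter inner ring diameter, mm.
#' @param timeResolutionFwhmNs coincidence time resolution FWHM, ns.
#' @param tcwNs time coincidence window tau, ns (default twice the FWHM).
#' @param dwDelayNs delayed-window offset, ns.
#' @param deadTimeNs paralysable dead-time constant, ns (0 disables; dead
#'   time is only applied when [applyDeadTime()] is called).
#' @return a [ScannerGeometry-class].
#' @examples
#' ring <- makeRing()
#' nDetectors(ring)
#' @export
makeRing <- function(nDetectors = 148L, ringDiameter = 94.2,
                     timeResolutionFwhmNs = 5,
                     tcwNs = 2 * timeResolutionFwhmNs,
                     dwDelayNs = 500, deadTimeNs = 300) {
  if (ringDiameter <= 0 || tcwNs <= 0 || dwDelayNs <= 0)
    stop("scanner dimensions and window parameters must be positive")
  new("ScannerGeometry",
      nDetectors = as.integer(nDetectors),
      ringDiameter = as.numeric(ringDiameter),
      timeResolutionFwhm = timeResolutionFwhmNs * 1e-9,
      tcw = tcwNs * 1e-9,
      dwDelay = dwDelayNs * 1e-9,
      deadTime = deadTimeNs * 1e-9)
}

#' Detector centre angles and positions
#'
#' Detector k sits at angle `(k - 1) * 2 * pi / n` on the ring circle.
#'
#' @param scanner a [ScannerGeometry-class].
#' @return `detectorAngles`: numeric vector of angles (rad);
#'   `detectorPositions`: n x 2 matrix of (x, y) in mm.
#' @export
detectorAngles <- function(scanner) {
  n <- nDetectors(scanner)
  (seq_len(n) - 1) * 2 * pi / n
}

#' @rdname detectorAngles
#' @export
detectorPositions <- function(scanner) {
  a <- detectorAngles(scanner)
  r <- ringDiameter(scanner) / 2
  cbind(x = r * cos(a), y = r * sin(a))
}

## detector hit by a photon arriving at ring angle theta
.detectorAt <- function(theta, n) {
  (as.integer(round(theta / (2 * pi / n))) %% n) + 1L
}

#' LoR linear indexing
#'
#' Bijection between canonical detector pairs (i, j), i < j, and linear LoR
#' indices l in 1 .. n(n-1)/2 (row-wise upper triangle).
#'
#' @param i,j 1-based detector indices (vectors allowed); `i < j` required.
#' @param l linear LoR indices.
#' @param n number of detectors.
#' @return `lorIndex`: integer vector of linear indices; `lorPair`: a
#'   two-column integer matrix with columns `i`, `j`; `nLors`: the number
#'   of LoRs, n(n-1)/2.
#' @examples
#' lorIndex(1, 2, 8)        # 1
#' lorPair(nLors(8), 8)     # (7, 8)
#' @export
lorIndex <- function(i, j, n) {
  stopifnot(all(i < j), all(i >= 1L), all(j <= n))
  as.integer((i - 1) * (2 * n - i) / 2 + (j - i))
}

#' @rdname lorIndex
#' @export
lorPair <- function(l, n) {
  stopifnot(all(l >= 1L), all(l <= n * (n - 1) / 2))
  cum <- cumsum((n - 1):1)           # last linear index with first index i
  i <- findInterval(l - 1L, cum) + 1L
  j <- l - c(0L, cum)[i] + i
  cbind(i = as.integer(i), j = as.integer(j))
}

#' @rdname lorIndex
#' @export
nLors <- function(n) as.integer(n * (n - 1) / 2)

#' LoR endpoint coordinates
#'
#' @param scanner a [ScannerGeometry-class].
#' @param l linear LoR indices (default all).
#' @return list with matrices `p0`, `p1` (mm) holding the chord endpoints.
#' @export
lorEndpoints <- function(scanner, l = seq_len(nLors(nDetectors(scanner)))) {
  pos <- detectorPositions(scanner)
  ij <- lorPair(l, nDetectors(scanner))
  list(p0 = pos[ij[, 1L], , drop = FALSE],
       p1 = pos[ij[, 2L], , drop = FALSE])
}

## ---- phantoms -----------------------------------------------------------

## effective (carved) area of each primitive: later primitives override
## earlier ones where they overlap; inserts are assumed fully inside their
## parent disc.
.effectiveAreas <- function(pr) {
  k <- nrow(pr)
  area <- ifelse(pr$shape == "disc", pi * pr$radius^2, 0)
  eff <- area
  if (k > 1L) for (a in seq_len(k - 1L)) for (b in seq((a + 1L), k)) {
    d <- sqrt((pr$x[b] - pr$x[a])^2 + (pr$y[b] - pr$y[a])^2)
    if (d + pr$radius[b] <= pr$radius[a] + 1e-9)
      eff[a] <- eff[a] - area[b]
  }
  pmax(eff, 0)
}

## integral of concentration over the plane; point primitives contribute
## their concentration directly (interpreted as Bq at the point)
.phantomIntegral <- function(pr) {
  eff <- .effectiveAreas(pr)
  sum(ifelse(pr$shape == "point", pr$concentration, pr$concentration * eff))
}

.newPhantom <- function(pr, totalActivity, outsideFov = FALSE) {
  integ <- .phantomIntegral(pr)
  if (integ <= 0) stop("phantom has no activity")
  pr$concentration <- pr$concentration * totalActivity / integ
  new("PhantomSpec", primitives = pr,
      totalActivity = as.numeric(totalActivity),
      outsideFov = outsideFov)
}

#' Phantom constructors
#'
#' `discPhantom`: homogeneously active disc. `pointPhantom`: all activity at
#' one point. `iqPhantom`: image-quality phantom, a warm background disc
#' (diameter 48 mm) with a hot insert at `hotRatio` times the background
#' concentration and a cold (empty) insert, both of diameter 16 mm.
#' `outsideFovPhantom`: a source placed axially outside the ring, which can
#' deliver at most one photon of each pair to the detectors and therefore
#' produces no correlated singles.
#'
#' @param totalActivity total activity, Bq.
#' @param radius disc radius, mm.
#' @param center centre (x, y), mm.
#' @param backgroundRadius,insertRadius,insertOffset IQ geometry, mm.
#' @param hotRatio hot-to-background concentration ratio.
#' @return a [PhantomSpec-class].
#' @examples
#' iq <- iqPhantom(1e5)
#' totalActivity(iq)
#' @export
discPhantom <- function(totalActivity, radius = 24, center = c(0, 0)) {
  .newPhantom(data.frame(shape = "disc", x = center[1], y = center[2],
                         radius = radius, concentration = 1),
              totalActivity)
}

#' @rdname discPhantom
#' @export
pointPhantom <- function(totalActivity, center = c(0, 0)) {
  .newPhantom(data.frame(shape = "point", x = center[1], y = center[2],
                         radius = 0, concentration = 1),
              totalActivity)
}

#' @rdname discPhantom
#' @export
iqPhantom <- function(totalActivity, backgroundRadius = 24,
                      insertRadius = 8, insertOffset = 12, hotRatio = 4) {
  pr <- data.frame(
    shape = "disc",
    x = c(0, -insertOffset, insertOffset),
    y = c(0, 0, 0),
    radius = c(backgroundRadius, insertRadius, insertRadius),
    concentration = c(1, hotRatio, 0))
  .newPhantom(pr, totalActivity)
}

#' @rdname discPhantom
#' @export
outsideFovPhantom <- function(totalActivity, radius = 35) {
  .newPhantom(data.frame(shape = "disc", x = 0, y = 0, radius = radius,
                         concentration = 1),
              totalActivity, outsideFov = TRUE)
}

#' Activity concentration at points
#'
#' Evaluates the phantom's concentration map; where primitives overlap the
#' last listed primitive wins (inserts carve their parent). Point
#' primitives are singular and evaluate to 0 here.
#'
#' @param phantom a [PhantomSpec-class].
#' @param x,y coordinates, mm (vectors of equal length).
#' @return numeric vector of concentrations.
#' @export
concentrationAt <- function(phantom, x, y) {
  pr <- primitives(phantom)
  out <- numeric(length(x))
  for (k in seq_len(nrow(pr))) {
    if (pr$shape[k] != "disc") next
    inside <- (x - pr$x[k])^2 + (y - pr$y[k])^2 <= pr$radius[k]^2
    out[inside] <- pr$concentration[k]
  }
  out
}

## sample annihilation positions with density proportional to concentration
.samplePositions <- function(phantom, n) {
  pr <- primitives(phantom)
  eff <- .effectiveAreas(pr)
  w <- ifelse(pr$shape == "point", pr$concentration,
              pr$concentration * eff)
  if (all(w <= 0)) stop("phantom has no activity")
  prim <- sample.int(nrow(pr), n, replace = TRUE, prob = w)
  x <- numeric(n); y <- numeric(n)
  for (k in unique(prim)) {
    idx <- which(prim == k)
    if (pr$shape[k] == "point") {
      x[idx] <- pr$x[k]; y[idx] <- pr$y[k]
      next
    }
    m <- length(idx)
    got <- 0L
    while (got < m) {
      nb <- max(2L * (m - got), 64L)
      r <- pr$radius[k] * sqrt(runif(nb))
      a <- runif(nb, 0, 2 * pi)
      px <- pr$x[k] + r * cos(a); py <- pr$y[k] + r * sin(a)
      ## reject points owned by a later (overriding) primitive
      keep <- rep(TRUE, nb)
      if (k < nrow(pr)) for (m2 in seq(k + 1L, nrow(pr))) {
        if (pr$shape[m2] != "disc") next
        keep <- keep &
          ((px - pr$x[m2])^2 + (py - pr$y[m2])^2 > pr$radius[m2]^2)
      }
      px <- px[keep]; py <- py[keep]
      take <- min(length(px), m - got)
      if (take > 0L) {
        x[idx[got + seq_len(take)]] <- px[seq_len(take)]
        y[idx[got + seq_len(take)]] <- py[seq_len(take)]
        got <- got + take
      }
    }
  }
  cbind(x = x, y = y)
}

## trace back-to-back photon pairs from positions pos with emission angles
## phi to the ring; returns detector indices (n x 2)
.tracePairs <- function(pos, phi, scanner) {
  n <- nDetectors(scanner)
  r <- ringDiameter(scanner) / 2
  ux <- cos(phi); uy <- sin(phi)
  pu <- pos[, 1L] * ux + pos[, 2L] * uy
  disc <- pu^2 - (pos[, 1L]^2 + pos[, 2L]^2) + r^2
  s <- sqrt(pmax(disc, 0))
  t1 <- -pu + s                        # along +u
  t2 <- pu + s                         # along -u
  th1 <- atan2(pos[, 2L] + t1 * uy, pos[, 1L] + t1 * ux)
  th2 <- atan2(pos[, 2L] - t2 * uy, pos[, 1L] - t2 * ux)
  cbind(.detectorAt(th1 %% (2 * pi), n), .detectorAt(th2 %% (2 * pi), n))
}

.checkInsideBore <- function(scanner, phantom) {
  pr <- primitives(phantom)
  r <- ringDiameter(scanner) / 2
  reach <- sqrt(pr$x^2 + pr$y^2) + pr$radius
  if (any(reach >= r))
    stop("phantom must lie inside the scanner bore")
}

#' Derive the Poisson rate model of a phantom in a scanner
#'
#' Monte-Carlo estimate of the per-detector uncorrelated-singles rates
#' lambda_i and per-LoR correlated-pair rates rho_ij. Annihilation
#' positions are sampled proportionally to the activity concentration and
#' back-to-back photon pairs are emitted isotropically; each photon reaching
#' the ring is detected independently with probability `efficiency`.
#' Annihilations with exactly one detected photon contribute to lambda_i,
#' those with both detected to rho_ij. For an `outsideFov` phantom only one
#' photon of each pair can geometrically reach the ring, so rho is
#' identically zero and lambda is uniform across detectors with total
#' `totalActivity * efficiency`.
#'
#' @param scanner a [ScannerGeometry-class].
#' @param phantom a [PhantomSpec-class].
#' @param nMcRays number of sampled annihilations (>= 1e4).
#' @param efficiency per-photon detection probability in (0, 1].
#' @param seed optional RNG seed (set with [set.seed()]).
#' @return a [RateModel-class]; rates scale linearly with the phantom's
#'   total activity.
#' @export
deriveRateModel <- function(scanner, phantom, nMcRays = 1e5,
                            efficiency = 0.5, seed = NULL) {
  stopifnot(efficiency >= 0, efficiency <= 1)
  if (totalActivity(phantom) <= 0) stop("phantom activity must be positive")
  n <- nDetectors(scanner)
  if (phantom@outsideFov) {
    lam <- rep(totalActivity(phantom) * efficiency / n, n)
    return(rateModel(lam, matrix(0, n, n)))
  }
  if (nMcRays < 1e4) stop("nMcRays must be at least 1e4")
  .checkInsideBore(scanner, phantom)
  if (!is.null(seed)) set.seed(seed)
  nMcRays <- as.integer(nMcRays)
  pos <- .samplePositions(phantom, nMcRays)
  phi <- runif(nMcRays, 0, 2 * pi)
  det <- .tracePairs(pos, phi, scanner)
  d1 <- runif(nMcRays) < efficiency
  d2 <- runif(nMcRays) < efficiency
  w <- totalActivity(phantom) / nMcRays
  lam <- numeric(n)
  one <- xor(d1, d2)
  if (any(one)) {
    hit <- ifelse(d1[one], det[one, 1L], det[one, 2L])
    tb <- tabulate(hit, nbins = n)
    lam <- tb * w
  }
  rho <- matrix(0, n, n)
  both <- d1 & d2
  if (any(both)) {
    i <- pmin(det[both, 1L], det[both, 2L])
    j <- pmax(det[both, 1L], det[both, 2L])
    ok <- i != j                       # same-detector pairs are dropped
    if (any(ok)) {
      tb <- tabulate(lorIndex(i[ok], j[ok], n), nbins = nLors(n))
      ij <- lorPair(which(tb > 0L), n)
      rho[ij] <- tb[tb > 0L] * w
    }
  }
  rateModel(lam, rho)
}

#' Construct a rate model directly
#'
#' @param lambda per-detector uncorrelated-singles rates, counts/s.
#' @param rho per-LoR correlated-pair rates, pairs/s; either a symmetric
#'   matrix or upper-triangular storage (`rho[i, j]`, i < j).
#' @return a [RateModel-class].
#' @export
rateModel <- function(lambda, rho) {
  n <- length(lambda)
  rho <- as.matrix(rho)
  stopifnot(all(dim(rho) == n))
  low <- rho[lower.tri(rho)]
  if (any(low != 0)) {
    if (!isTRUE(all.equal(rho, t(rho))))
      stop("rho must be symmetric or upper-triangular")
    rho[lower.tri(rho, diag = TRUE)] <- 0
  } else diag(rho) <- 0
  new("RateModel", lambda = as.numeric(lambda), rho = rho)
}

#' Scale a rate model to a different total activity
#'
#' All rates are linear in the source activity, so rescaling is exact.
#'
#' @param model a [RateModel-class].
#' @param factor multiplicative activity factor.
#' @return a [RateModel-class].
#' @export
scaleRateModel <- function(model, factor) {
  stopifnot(factor >= 0)
  rateModel(model@lambda * factor, model@rho * factor)
}

#' Which LoRs pass through the phantom?
#'
#' A LoR passes through the phantom when its chord (between the two detector
#' centres) intersects any primitive with positive concentration. Used to
#' restrict the randoms term of the noise-equivalent count rate.
#'
#' @param scanner a [ScannerGeometry-class].
#' @param phantom a [PhantomSpec-class].
#' @param l linear LoR indices (default all).
#' @return logical vector along `l`.
#' @export
lorThroughPhantom <- function(scanner, phantom,
                              l = seq_len(nLors(nDetectors(scanner)))) {
  ep <- lorEndpoints(scanner, l)
  pr <- primitives(phantom)
  pr <- pr[pr$concentration > 0, , drop = FALSE]
  out <- rep(FALSE, length(l))
  d <- ep$p1 - ep$p0
  len2 <- rowSums(d^2)
  for (k in seq_len(nrow(pr))) {
    t <- ((pr$x[k] - ep$p0[, 1L]) * d[, 1L] +
          (pr$y[k] - ep$p0[, 2L]) * d[, 2L]) / len2
    t <- pmin(pmax(t, 0), 1)
    dx <- ep$p0[, 1L] + t * d[, 1L] - pr$x[k]
    dy <- ep$p0[, 2L] + t * d[, 2L] - pr$y[k]
    out <- out | (dx^2 + dy^2 <= max(pr$radius[k], 1e-6)^2)
  }
  out
}
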