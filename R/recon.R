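## Toy 2D ML-EM reconstruction with per-LoR additive randoms compensation,
## plus image-quality figures of merit.

#' Reconstruction grid
#'
#' Square pixel grid of `n` x `n` pixels spanning `fov` mm, centred on the
#' scanner axis.
#'
#' @param n pixels per side.
#' @param fov grid width, mm.
#' @return a [ReconGrid-class].
#' @export
reconGrid <- function(n = 64L, fov = 64) {
  new("ReconGrid", n = as.integer(n), fov = as.numeric(fov))
}

#' Pixel centre coordinates
#'
#' @param grid a [ReconGrid-class].
#' @return list with vectors `x`, `y` (mm) of the pixel-centre coordinates
#'   along one axis; pixel `v = ix + (iy - 1) * n` has centre
#'   `(x[ix], y[iy])`.
#' @export
gridCenters <- function(grid) {
  h <- pixelSize(grid)
  x <- -grid@fov / 2 + (seq_len(grid@n) - 0.5) * h
  list(x = x, y = x)
}

#' Build the sparse system matrix by exact chord-pixel intersection
#'
#' `A[l, v]` is the intersection length (mm) of LoR chord `l` with pixel
#' `v`, computed by exact ray tracing (pixel-boundary crossings along the
#' chord). Deterministic; the row sum of each LoR equals the length of its
#' chord inside the grid bounds.
#'
#' @param scanner a [ScannerGeometry-class].
#' @param grid a [ReconGrid-class].
#' @return a `Matrix::dgCMatrix` of dimension `nLors(n)` x `n^2`; pixels
#'   are indexed column-major with x fastest, matching
#'   `imageValues()[ix, iy]`.
#' @export
buildSystemMatrix <- function(scanner, grid) {
  n <- grid@n
  h <- pixelSize(grid)
  x0 <- -grid@fov / 2
  nL <- nLors(nDetectors(scanner))
  ep <- lorEndpoints(scanner)
  planes <- x0 + (0:n) * h
  li <- vector("list", nL)
  vi <- vector("list", nL)
  xi <- vector("list", nL)
  for (l in seq_len(nL)) {
    p0 <- ep$p0[l, ]; p1 <- ep$p1[l, ]
    d <- p1 - p0
    len <- sqrt(sum(d^2))
    ## clip the parametric range to the grid box (Liang-Barsky)
    tmin <- 0; tmax <- 1
    ok <- TRUE
    for (ax in 1:2) {
      if (d[ax] != 0) {
        tt <- (c(x0, x0 + grid@fov) - p0[ax]) / d[ax]
        tmin <- max(tmin, min(tt)); tmax <- min(tmax, max(tt))
      } else if (p0[ax] < x0 || p0[ax] > x0 + grid@fov) ok <- FALSE
    }
    if (!ok || tmin >= tmax) next
    tx <- if (d[1L] != 0) (planes - p0[1L]) / d[1L] else numeric(0)
    ty <- if (d[2L] != 0) (planes - p0[2L]) / d[2L] else numeric(0)
    ts <- c(tmin, tmax, tx[tx > tmin & tx < tmax], ty[ty > tmin & ty < tmax])
    ts <- sort(ts)
    seg <- diff(ts) * len
    mid <- (ts[-1L] + ts[-length(ts)]) / 2
    keep <- seg > len * 1e-12
    if (!any(keep)) next
    seg <- seg[keep]; mid <- mid[keep]
    ix <- pmin(pmax(floor((p0[1L] + mid * d[1L] - x0) / h) + 1, 1), n)
    iy <- pmin(pmax(floor((p0[2L] + mid * d[2L] - x0) / h) + 1, 1), n)
    li[[l]] <- rep.int(l, length(seg))
    vi[[l]] <- as.integer(ix + (iy - 1) * n)
    xi[[l]] <- seg
  }
  Matrix::sparseMatrix(i = unlist(li), j = unlist(vi), x = unlist(xi),
                       dims = c(nL, n * n))
}

#' Prompt counts per LoR as a vector
#'
#' Bins the sorted prompts into the linear LoR index, the `y_l` sinogram
#' data of the reconstruction.
#'
#' @param promptSet a [PromptSet-class].
#' @return integer vector of length `nLors(n)`.
#' @export
promptCountVector <- function(promptSet) {
  stopifnot(is(promptSet, "PromptSet"))
  n <- nrow(promptSet@counts)
  promptSet@counts[lorPair(seq_len(nLors(n)), n)]
}

#' Expected randoms counts per LoR
#'
#' Converts a rate estimate to the additive expected-counts term `r_l` of
#' the ML-EM forward model: `r_l = R_l * duration`. DW and ideal estimates
#' derive from integer coincidence counts, so their `r_l` are integers; SP
#' and SR produce real values, which is what lets them compensate
#' low-statistics LoRs whose expected randoms are below one count.
#'
#' @param estimate a [RandomsEstimate-class].
#' @param duration acquisition time, s (defaults to the estimate's own).
#' @return numeric vector of expected counts per linear LoR index.
#' @export
expectedRandomsCounts <- function(estimate, duration = NULL) {
  stopifnot(is(estimate, "RandomsEstimate"))
  if (is.null(duration)) duration <- estimate@duration
  if (!is.finite(duration))
    stop("duration needed to convert rates to expected counts")
  lorRateVector(estimate) * duration
}

#' ML-EM reconstruction with additive randoms term
#'
#' Iterates
#' `f_v <- f_v / sum_l(A_lv) * sum_l(y_l / q_l * A_lv)` with
#' `q_l = sum_w(A_lw f_w) + r_l`. Non-negativity is preserved by
#' construction; forward projections are floored at a tiny positive value
#' where a measured LoR would otherwise divide by zero.
#'
#' @param y integer prompt counts per LoR (see [promptCountVector()]).
#' @param A system matrix from [buildSystemMatrix()].
#' @param r expected randoms counts per LoR (scalar 0 or vector; see
#'   [expectedRandomsCounts()]).
#' @param grid the [ReconGrid-class] of `A`.
#' @param nIterations iterations to run.
#' @param init positive initial voxel value.
#' @param keepIterations iterations at which to store intermediate images.
#' @return a [ReconImage-class].
#' @export
mlem <- function(y, A, r = 0, grid, nIterations = 40L, init = 1,
                 keepIterations = integer(0)) {
  stopifnot(length(y) == nrow(A), init > 0, all(y >= 0))
  if (length(r) == 1L) r <- rep(as.numeric(r), length(y))
  stopifnot(length(r) == length(y), all(r >= 0))
  sens <- Matrix::colSums(A)
  pos <- sens > 0
  f <- rep(as.numeric(init), ncol(A))
  f[!pos] <- 0
  history <- list()
  for (k in seq_len(nIterations)) {
    q <- as.vector(A %*% f) + r
    q <- pmax(q, 1e-12)
    back <- as.vector(Matrix::crossprod(A, y / q))
    f[pos] <- f[pos] * back[pos] / sens[pos]
    if (k %in% keepIterations)
      history[[as.character(k)]] <- matrix(f, grid@n, grid@n)
  }
  new("ReconImage", values = matrix(f, grid@n, grid@n), grid = grid,
      iterations = as.integer(nIterations), history = history)
}

#' Poisson log-likelihood of an image given sinogram data
#'
#' `sum_l (y_l log q_l - q_l)` with `q = A f + r`; the EM objective,
#' non-decreasing across [mlem()] iterations.
#'
#' @param y,A,r as in [mlem()].
#' @param f voxel intensity vector or [ReconImage-class].
#' @return scalar log-likelihood (up to the y! constant).
#' @export
mlemLogLik <- function(y, A, f, r = 0) {
  if (is(f, "ReconImage")) f <- as.vector(imageValues(f))
  q <- pmax(as.vector(A %*% f) + r, 1e-300)
  sum(y * log(q) - q)
}

#' Rasterise a phantom onto a grid
#'
#' Evaluates the activity concentration at pixel centres; the reference
#' ("true") image for contrast-recovery and bias figures of merit.
#'
#' @param phantom a [PhantomSpec-class].
#' @param grid a [ReconGrid-class].
#' @return numeric matrix `n` x `n`.
#' @export
trueImage <- function(phantom, grid) {
  gc <- gridCenters(grid)
  xy <- expand.grid(x = gc$x, y = gc$y)
  matrix(concentrationAt(phantom, xy$x, xy$y), grid@n, grid@n)
}

#' Regions of interest for the image-quality phantom
#'
#' Circular hot and cold RoIs of radius `shrink` times the insert radius at
#' the insert centres, and a warm RoI in the homogeneous background chosen
#' away from the inserts and the phantom boundary so that every RoI lies
#' strictly inside a homogeneous region (avoiding border and resolution
#' effects).
#'
#' @param grid a [ReconGrid-class].
#' @param backgroundRadius,insertRadius,insertOffset IQ geometry, mm
#'   (defaults match [iqPhantom()]).
#' @param shrink RoI-to-insert radius ratio.
#' @param warmFraction warm RoI outer boundary as a fraction of the
#'   background radius.
#' @param warmMargin clearance between the warm RoI and the inserts, mm.
#' @return list of integer pixel-index vectors `hot`, `cold`, `warm`.
#' @export
iqRois <- function(grid, backgroundRadius = 24, insertRadius = 8,
                   insertOffset = 12, shrink = 0.6, warmFraction = 0.85,
                   warmMargin = 3) {
  gc <- gridCenters(grid)
  xy <- expand.grid(x = gc$x, y = gc$y)
  rr <- shrink * insertRadius
  hot <- which((xy$x + insertOffset)^2 + xy$y^2 <= rr^2)
  cold <- which((xy$x - insertOffset)^2 + xy$y^2 <= rr^2)
  dHot <- sqrt((xy$x + insertOffset)^2 + xy$y^2)
  dCold <- sqrt((xy$x - insertOffset)^2 + xy$y^2)
  warm <- which(sqrt(xy$x^2 + xy$y^2) <= warmFraction * backgroundRadius &
                dHot > insertRadius + warmMargin &
                dCold > insertRadius + warmMargin)
  if (!length(hot) || !length(cold) || !length(warm))
    stop("empty RoI: grid too coarse for the requested RoI geometry")
  list(hot = hot, cold = cold, warm = warm)
}

.roiMean <- function(img, idx) mean(img[idx])

#' Image-quality figures of merit
#'
#' Computes, over the hot/cold/warm RoIs: contrast
#' `C = mu_hot / mu_warm - 1`; contrast recovery coefficient
#' `CRC = C / C_true`; spill-over ratio `SOR = mu_cold / mu_warm`; image
#' roughness `IR = sum((f - mu)^2) / mu / (V - 1)` per RoI; regional bias
#' `RB = mu_r / mu_t - 1` per RoI (undefined for the cold RoI whose true
#' mean is zero).
#'
#' Contrast, CRC and SOR are intensity-ratio quantities and do not depend
#' on the absolute scale of either image; for the regional bias the true
#' image is first rescaled to the reconstruction's total intensity so that
#' `RB` measures regional misallocation rather than the arbitrary
#' counts-versus-concentration unit mismatch.
#'
#' @param image a [ReconImage-class] or numeric matrix.
#' @param truth the reference image matrix (see [trueImage()]).
#' @param rois RoI list from [iqRois()].
#' @return list with elements `C`, `CRC`, `SOR`, `IR` (named vector), `RB`
#'   (named vector) and the RoI means `muRecon`, `muTrue` (the latter on
#'   the rescaled truth).
#' @export
computeFoms <- function(image, truth, rois) {
  f <- if (is(image, "ReconImage")) imageValues(image) else image
  stopifnot(all(dim(f) == dim(truth)))
  if (sum(truth) > 0) truth <- truth * sum(f) / sum(truth)
  muR <- vapply(rois, .roiMean, numeric(1), img = f)
  muT <- vapply(rois, .roiMean, numeric(1), img = truth)
  if (muR[["warm"]] <= 0) stop("zero background mean: FoMs undefined")
  C <- muR[["hot"]] / muR[["warm"]] - 1
  Ct <- muT[["hot"]] / muT[["warm"]] - 1
  ir <- vapply(names(rois), function(a) {
    v <- f[rois[[a]]]
    if (length(v) < 2L || mean(v) <= 0) return(NA_real_)
    sum((v - mean(v))^2) / mean(v) / (length(v) - 1)
  }, numeric(1))
  rb <- ifelse(muT > 0, muR / muT - 1, NA_real_)
  names(rb) <- names(rois)
  list(C = C, CRC = C / Ct, SOR = muR[["cold"]] / muR[["warm"]],
       IR = ir, RB = rb, muRecon = muR, muTrue = muT)
}

#' Correlation coefficient between two images
#'
#' Uncentred cosine similarity
#' `sum(a * b) / sqrt(sum(a^2) * sum(b^2))`; 1 for identical images up to
#' scale, 0 for disjoint supports.
#'
#' @param recon,truth numeric matrices/vectors of equal size (a
#'   [ReconImage-class] is accepted).
#' @return scalar in `[0, 1]` for non-negative images.
#' @export
correlationCoefficient <- function(recon, truth) {
  if (is(recon, "ReconImage")) recon <- imageValues(recon)
  if (is(truth, "ReconImage")) truth <- imageValues(truth)
  a <- as.vector(recon); b <- as.vector(truth)
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("correlation undefined for an all-zero image")
  sum(a * b) / (na * nb)
}
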