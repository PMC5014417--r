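## On-disk formats: singles list-mode TSV, sparse LoR triplet tables, rate
## model tables, image grids, and the YAML experiment configuration. All
## files carry a '#'-prefixed header with a schema version; times on disk
## are in seconds (configs accept nanoseconds and convert at parse time).

.SCHEMA_VERSION <- 1L

.writeHeader <- function(path, kind, meta) {
  lines <- c(sprintf("# randcoinc %s v%d", kind, .SCHEMA_VERSION),
             vapply(names(meta), function(k)
               sprintf("# %s: %s", k, format(meta[[k]], digits = 17)),
               character(1)))
  writeLines(lines, path)
  length(lines)
}

.readHeader <- function(path, kind) {
  lines <- character()
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    l <- readLines(con, n = 1L)
    if (!length(l) || !startsWith(l, "#")) break
    lines <- c(lines, l)
  }
  if (!length(lines)) stop("missing header in ", path)
  m <- regmatches(lines[1L],
                  regexec("^# randcoinc (\\S+) v(\\d+)$", lines[1L]))[[1L]]
  if (length(m) != 3L || m[2L] != kind)
    stop(sprintf("%s: expected a '%s' file, found '%s'", path, kind,
                 lines[1L]))
  if (as.integer(m[3L]) > .SCHEMA_VERSION)
    stop(sprintf("%s: schema v%s is newer than this package understands (v%d)",
                 path, m[3L], .SCHEMA_VERSION))
  meta <- list()
  for (l in lines[-1L]) {
    kv <- regmatches(l, regexec("^# (\\S+): (.*)$", l))[[1L]]
    if (length(kv) == 3L) meta[[kv[2L]]] <- kv[3L]
  }
  list(meta = meta, skip = length(lines))
}

#' Read and write singles list-mode streams
#'
#' Tab-separated singles list-mode file with a commented header carrying
#' the schema version, acquisition duration, ring size and seed. Columns:
#' `time` (s), `detector`, `annihilationId`, `photonIndex`. The round trip
#' `readSinglesStream(writeSinglesStream(x))` is lossless.
#'
#' @param stream a [SinglesStream-class].
#' @param path file path.
#' @return `writeSinglesStream`: the path, invisibly;
#'   `readSinglesStream`: a [SinglesStream-class].
#' @export
writeSinglesStream <- function(stream, path) {
  stopifnot(is(stream, "SinglesStream"))
  seed <- stream@provenance$seed
  .writeHeader(path, "singles",
               list(duration = stream@duration,
                    n_detectors = stream@nDetectors,
                    seed = if (is.null(seed)) NA else seed))
  data.table::fwrite(stream@events, path, sep = "\t", append = TRUE,
                     col.names = TRUE)
  invisible(path)
}

#' @rdname writeSinglesStream
#' @export
readSinglesStream <- function(path) {
  h <- .readHeader(path, "singles")
  ev <- as.data.frame(data.table::fread(path, skip = h$skip, sep = "\t",
                                        header = TRUE))
  need <- c("time", "detector", "annihilationId", "photonIndex")
  if (!all(need %in% names(ev)))
    stop(path, ": malformed singles table, need columns ",
         paste(need, collapse = ", "))
  ev$detector <- as.integer(ev$detector)
  ev$annihilationId <- as.integer(ev$annihilationId)
  ev$photonIndex <- as.integer(ev$photonIndex)
  seed <- suppressWarnings(as.integer(h$meta$seed))
  .newStream(ev[need], as.numeric(h$meta$duration),
             as.integer(h$meta$n_detectors),
             provenance = list(seed = if (is.na(seed)) NULL else seed,
                               source = path))
}

#' Read and write sparse per-LoR triplet tables
#'
#' Triplet format `(i, j, value)` with canonical i < j, one row per
#' nonzero LoR, plus a commented header (`kind` tags what the values are:
#' prompt counts, randoms rates, ...). Duplicate `(i, j)` rows are
#' rejected on read.
#'
#' @param mat upper-triangular numeric matrix.
#' @param path file path.
#' @param kind free-form content tag stored in the header.
#' @param meta named list of extra header fields (duration, tcw, ...).
#' @return `writeLorTable`: the path, invisibly; `readLorTable`: list with
#'   `matrix` and `meta`.
#' @export
writeLorTable <- function(mat, path, kind = "values", meta = list()) {
  n <- nrow(mat)
  .writeHeader(path, "lortable",
               c(list(kind = kind, n_detectors = n), meta))
  nz <- which(upper.tri(mat) & mat != 0, arr.ind = TRUE)
  df <- data.frame(i = nz[, 1L], j = nz[, 2L], value = mat[nz])
  df <- df[order(df$i, df$j), ]
  data.table::fwrite(df, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname writeLorTable
#' @export
readLorTable <- function(path) {
  h <- .readHeader(path, "lortable")
  df <- as.data.frame(data.table::fread(path, skip = h$skip, sep = "\t",
                                        header = TRUE))
  n <- as.integer(h$meta$n_detectors)
  if (any(df$i >= df$j) || any(df$i < 1L) || any(df$j > n))
    stop(path, ": triplet rows must satisfy 1 <= i < j <= n")
  if (anyDuplicated(df[c("i", "j")]))
    stop(path, ": duplicate (i, j) rows")
  m <- matrix(0, n, n)
  m[cbind(df$i, df$j)] <- df$value
  list(matrix = m, meta = h$meta)
}

#' Read and write rate models
#'
#' Two columnar files: `(detector, lambda)` for the uncorrelated rates and
#' an `(i, j, rho)` triplet table for the correlated-pair rates.
#'
#' @param model a [RateModel-class].
#' @param lambdaPath,rhoPath file paths.
#' @return `writeRateModel`: invisibly `NULL`; `readRateModel`: a
#'   [RateModel-class].
#' @export
writeRateModel <- function(model, lambdaPath, rhoPath) {
  stopifnot(is(model, "RateModel"))
  n <- nDetectors(model)
  .writeHeader(lambdaPath, "lambda", list(n_detectors = n))
  data.table::fwrite(data.frame(detector = seq_len(n),
                                lambda = model@lambda),
                     lambdaPath, sep = "\t", append = TRUE,
                     col.names = TRUE)
  writeLorTable(model@rho, rhoPath, kind = "rho")
  invisible(NULL)
}

#' @rdname writeRateModel
#' @export
readRateModel <- function(lambdaPath, rhoPath) {
  h <- .readHeader(lambdaPath, "lambda")
  df <- as.data.frame(data.table::fread(lambdaPath, skip = h$skip,
                                        sep = "\t", header = TRUE))
  n <- as.integer(h$meta$n_detectors)
  lam <- numeric(n)
  lam[df$detector] <- df$lambda
  rateModel(lam, readLorTable(rhoPath)$matrix)
}

#' Write an image as a plain-text grid
#'
#' Flat TSV of intensities with a commented header (grid size, pixel
#' size, iteration count).
#'
#' @param image a [ReconImage-class].
#' @param path file path.
#' @return the path, invisibly.
#' @export
writeImage <- function(image, path) {
  stopifnot(is(image, "ReconImage"))
  .writeHeader(path, "image",
               list(n = image@grid@n, fov_mm = image@grid@fov,
                    iterations = image@iterations))
  data.table::fwrite(as.data.frame(imageValues(image)), path, sep = "\t",
                     append = TRUE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeImage
#' @export
readImage <- function(path) {
  h <- .readHeader(path, "image")
  m <- as.matrix(data.table::fread(path, skip = h$skip, sep = "\t",
                                   header = FALSE))
  dimnames(m) <- NULL
  new("ReconImage", values = m,
      grid = reconGrid(as.integer(h$meta$n), as.numeric(h$meta$fov_mm)),
      iterations = as.integer(h$meta$iterations), history = list())
}

## ---- experiment configuration ------------------------------------------

#' Read an experiment configuration file
#'
#' YAML with nested sections `scanner`, `phantom`, `simulation`, `sorter`,
#' `methods`, `recon`. Times are given in nanoseconds in the file and
#' converted to seconds here. Missing fields fall back to the package
#' defaults (148-detector, 94.2 mm ring; tau = 10 ns; 500 ns delay).
#'
#' @param path YAML file path.
#' @return list with `scanner` ([ScannerGeometry-class]), `phantom`
#'   ([PhantomSpec-class]), `simulation`, `methods`, `recon` and the raw
#'   config plus its md5 `hash`.
#' @export
readConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  num <- function(x, default) if (is.null(x)) default else as.numeric(x)
  sc <- raw$scanner
  scanner <- makeRing(
    nDetectors = num(sc$n_detectors, 148),
    ringDiameter = num(sc$ring_diameter_mm, 94.2),
    timeResolutionFwhmNs = num(sc$time_resolution_fwhm_ns, 5),
    tcwNs = num(sc$tcw_ns, 2 * num(sc$time_resolution_fwhm_ns, 5)),
    dwDelayNs = num(sc$dw_delay_ns, 500),
    deadTimeNs = num(sc$dead_time_ns, 300))
  ph <- raw$phantom
  act <- num(ph$total_activity_bq, 1e5)
  phantom <- switch(ph$type %||% "iq",
    iq = iqPhantom(act,
                   backgroundRadius = num(ph$background_radius_mm, 24),
                   insertRadius = num(ph$insert_radius_mm, 8),
                   insertOffset = num(ph$insert_offset_mm, 12),
                   hotRatio = num(ph$hot_ratio, 4)),
    disc = discPhantom(act, radius = num(ph$radius_mm, 24)),
    point = pointPhantom(act),
    outside = outsideFovPhantom(act, radius = num(ph$radius_mm, 35)),
    stop("unknown phantom type: ", ph$type))
  sim <- raw$simulation %||% list()
  simulation <- list(
    level = sim$level %||% "annihilation",
    duration = num(sim$duration_s, 1),
    efficiency = num(sim$efficiency, 0.5),
    nMcRays = num(sim$n_mc_rays, 1e5),
    seed = as.integer(num(sim$seed, 1)),
    jitter = isTRUE(sim$jitter),
    deadTime = isTRUE(sim$dead_time))
  rec <- raw$recon %||% list()
  recon <- list(
    enabled = isTRUE(rec$enabled),
    nPixels = as.integer(num(rec$n_pixels, 64)),
    fov = num(rec$fov_mm, 64),
    iterations = as.integer(num(rec$iterations, 40)))
  list(scanner = scanner, phantom = phantom, simulation = simulation,
       methods = toupper(raw$methods %||% c("SR", "DW", "SP", "IDEAL")),
       recon = recon, raw = raw,
       hash = unname(tools::md5sum(path)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
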