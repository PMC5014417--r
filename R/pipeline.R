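## End-to-end experiment driver: simulate -> (jitter / dead time) -> sort
## (SW, DW) -> classify -> estimate -> metrics -> optional reconstruction.
## Every stage's output lands in the output directory in the documented
## text formats, and a JSON-lines log records counts, rates and solver
## diagnostics.

.logLine <- function(con, stage, ...) {
  rec <- c(list(stage = stage), list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
}

#' Run the full estimation pipeline
#'
#' Executes one acquisition end to end under a single master seed:
#' simulate a labeled singles stream (annihilation- or model-level),
#' optionally apply time jitter and paralysable dead time, sort prompts
#' with the single-window sorter, classify against ground truth, estimate
#' randoms with the requested methods, write all tables, and (optionally)
#' reconstruct the randoms-compensated images and their figures of merit.
#' Identical seeds give byte-identical event files.
#'
#' @param config a configuration list from [readConfig()] (or a path to a
#'   YAML file, which is read first).
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results (`stream`,
#'   `promptSet`, `estimates`, `metrics`, and `recon` when enabled).
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) config <- readConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  scanner <- config$scanner
  phantom <- config$phantom
  sim <- config$simulation
  methods <- intersect(config$methods, c("SR", "DW", "SP", "IDEAL"))
  log <- file(file.path(outDir, "pipeline.jsonl"), "w")
  on.exit(close(log))
  hash <- config$hash %||% NA_character_
  .logLine(log, "config", hash = hash, seed = sim$seed,
           methods = methods)

  ## simulate
  if (identical(sim$level, "model") || phantom@outsideFov) {
    model <- deriveRateModel(scanner, phantom, nMcRays = sim$nMcRays,
                             efficiency = sim$efficiency,
                             seed = childSeed(sim$seed, 1L))
    writeRateModel(model, file.path(outDir, "lambda.tsv"),
                   file.path(outDir, "rho.tsv"))
    stream <- simulateModelStream(model, sim$duration,
                                  seed = childSeed(sim$seed, 2L))
  } else {
    stream <- simulateAnnihilationStream(scanner, phantom, sim$duration,
                                         efficiency = sim$efficiency,
                                         seed = childSeed(sim$seed, 2L))
  }
  if (sim$jitter)
    stream <- applyTimeJitter(stream, timeResolutionFwhm(scanner),
                              seed = childSeed(sim$seed, 3L))
  if (sim$deadTime && deadTime(scanner) > 0)
    stream <- applyDeadTime(stream, deadTime(scanner))
  writeSinglesStream(stream, file.path(outDir, "singles.tsv"))
  .logLine(log, "simulate", n_events = nrow(events(stream)),
           duration = duration(stream))

  ## sort + classify
  ps <- classifyPrompts(swSort(stream, tcw(scanner)))
  writeLorTable(promptCounts(ps), file.path(outDir, "prompts.tsv"),
                kind = "prompts",
                meta = list(duration = duration(ps), tcw = tcw(scanner),
                            n_multiples = nMultiplesDiscarded(ps)))
  .logLine(log, "sort", n_prompts = nrow(prompts(ps)),
           n_multiples = nMultiplesDiscarded(ps),
           n_same_detector = ps@nSameDetector,
           n_trues = sum(trueCounts(ps)), n_randoms = sum(randomCounts(ps)))

  ## estimate
  si <- singlesRates(stream)
  est <- list()
  if ("SR" %in% methods)
    est$SR <- estimateSR(si, tcw(scanner), duration(stream))
  if ("SP" %in% methods) {
    est$SP <- estimateSP(si, ps, tcw(scanner))
    d <- spDiagnostics(est$SP)
    .logLine(log, "sp_solver", lambda_hat = d$lambdaHat,
             Lambda_hat = d$LambdaHat, tau_eff = d$tauEff,
             n_clamped = d$nClamped)
  }
  if ("DW" %in% methods)
    est$DW <- dwSort(stream, tcw(scanner), dwDelay(scanner))
  if ("IDEAL" %in% methods)
    est$ideal <- estimateIdeal(ps)
  for (nm in names(est))
    writeLorTable(lorRates(est[[nm]]),
                  file.path(outDir, sprintf("randoms_%s.tsv", tolower(nm))),
                  kind = sprintf("randoms-rate-%s", nm),
                  meta = list(duration = duration(stream)))

  ## metrics
  mask <- if (phantom@outsideFov) rep(TRUE, nLors(nDetectors(scanner)))
          else lorThroughPhantom(scanner, phantom)
  met <- data.frame(
    method = names(est),
    randomsTotal = vapply(est, totalRate, numeric(1)),
    randomsPhantom = vapply(est, function(e)
      sum(lorRateVector(e)[mask]), numeric(1)),
    row.names = NULL)
  met$promptsRate <- nrow(prompts(ps)) / duration(ps)
  met$randomsFraction <- randomsFraction(ps)
  data.table::fwrite(met, file.path(outDir, "metrics.tsv"), sep = "\t")
  .logLine(log, "metrics", randoms_fraction = met$randomsFraction[1L])

  ## optional reconstruction
  rec <- NULL
  if (isTRUE(config$recon$enabled)) {
    grid <- reconGrid(config$recon$nPixels, config$recon$fov)
    A <- buildSystemMatrix(scanner, grid)
    y <- promptCountVector(ps)
    truth <- trueImage(phantom, grid)
    rec <- list(grid = grid, images = list(), foms = list())
    for (nm in names(est)) {
      r <- expectedRandomsCounts(est[[nm]], duration(stream))
      img <- mlem(y, A, r, grid, nIterations = config$recon$iterations)
      writeImage(img, file.path(outDir, sprintf("image_%s.tsv",
                                                tolower(nm))))
      rec$images[[nm]] <- img
    }
    .logLine(log, "recon", iterations = config$recon$iterations,
             methods = names(est))
  }
  invisible(list(stream = stream, promptSet = ps, estimates = est,
                 metrics = met, recon = rec))
}
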