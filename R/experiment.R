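#' Assemble and validate an experiment configuration
#'
#' A fully serializable description of one closed-loop experiment:
#' code generation, feedback map, eligibility trace, learning and mirroring
#' parameters plus a single seed from which all per-stage seeds are derived.
#' Validation happens before any computation; in particular the loop delay
#' must be an integer multiple of the bin width.
#'
#' @param seed integer master seed.
#' @param code list: \code{kind} ("variable"/"stereotyped"), \code{nNeurons},
#'   \code{t0}, \code{dt}, \code{renditionLen}, \code{renditionsPerEpoch},
#'   and for stereotyped codes \code{interBurstLag}, \code{cycles}.
#' @param map list: \code{nSensory}, \code{tauM}, \code{tauA},
#'   \code{conditionCap}, or \code{qCsv} (path to a stored map).
#' @param trace list: \code{kind}, \code{e0}, \code{decayTime},
#'   \code{support}.
#' @param learning list: \code{rateScale}, \code{nEpochs},
#'   \code{convergenceTol}, \code{tailFrac}.
#' @param mirroring list: \code{maxLag}, \code{nNull}.
#' @return validated config list (class \code{"mirrorloopConfig"}).
#' @export
experimentConfig <- function(seed = 1L, code = list(), map = list(),
                             trace = list(), learning = list(),
                             mirroring = list()) {
  code <- utils::modifyList(list(kind = "variable", nNeurons = 4L, t0 = 10,
                                 dt = 1, renditionLen = 8000,
                                 renditionsPerEpoch = 40L,
                                 interBurstLag = 20, cycles = 1L,
                                 burstRate = 1L), code)
  map <- utils::modifyList(list(nSensory = code$nNeurons, tauM = 25,
                                tauA = 15, conditionCap = 5, qCsv = NULL),
                           map)
  tau <- map$tauM + map$tauA
  trace <- utils::modifyList(list(kind = "exponential", e0 = 1,
                                  decayTime = 2 * tau, support = NULL),
                             trace)
  learning <- utils::modifyList(list(rateScale = 0.5, nEpochs = 60L,
                                     convergenceTol = 1e-4, tailFrac = 0.3),
                                learning)
  mirroring <- utils::modifyList(list(maxLag = 100, nNull = 0L), mirroring)

  if (!code$kind %in% c("variable", "stereotyped"))
    stop("config: unknown code kind '", code$kind, "'")
  msToBins(tau, code$dt, "tau")            # must hold before any compute
  msToBins(code$t0, code$dt, "t0")
  if (code$kind == "stereotyped")
    msToBins(code$interBurstLag, code$dt, "interBurstLag")
  cfg <- list(seed = as.integer(seed), code = code, map = map,
              trace = trace, learning = learning, mirroring = mirroring)
  class(cfg) <- "mirrorloopConfig"
  cfg
}

#' Read an experiment configuration from YAML or JSON
#'
#' @param path file path (.yaml/.yml or .json).
#' @return validated config, see \code{\link{experimentConfig}}.
#' @export
readExperimentConfig <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    read_json(path, simplifyVector = TRUE)
  do.call(experimentConfig, raw)
}

#' Run a full closed-loop experiment
#'
#' Pipeline: generate the motor code, draw (or load) the feedback map, learn
#' the inverse model, run the mirroring experiment, and write all artifacts
#' (weights, correlograms, offsets, JSON report) to a run directory.  The
#' report contains the per-neuron offsets and gains, the closed-form
#' agreement of the learned weights, and the offset-dichotomy verdict
#' (offset near the loop delay = causal inverse; near zero = predictive).
#' All randomness derives from the config seed; identical config + seed
#' reproduce identical artifacts.
#'
#' @param config a config from \code{\link{experimentConfig}} /
#'   \code{\link{readExperimentConfig}}.
#' @param outDir run directory, created if needed (NULL: nothing written).
#' @param verbose log stage progress and timings via \code{message()}.
#' @return the report, invisibly.
#' @export
runExperiment <- function(config, outDir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "mirrorloopConfig"))
  log <- function(...) if (verbose) message(format(Sys.time(), "%H:%M:%S "),
                                            sprintf(...))
  tic <- function() proc.time()[["elapsed"]]
  timings <- list()
  seed <- config$seed

  t1 <- tic()
  tr <- config$trace
  trace <- eligibilityTrace(tr$kind, e0 = tr$e0, decayTime = tr$decayTime,
                            support = tr$support)
  mp <- config$map
  map <- if (!is.null(mp$qCsv)) readMap(mp$qCsv) else
    randomInvertibleMap(config$code$nNeurons, mp$nSensory, tauM = mp$tauM,
                        tauA = mp$tauA, conditionCap = mp$conditionCap,
                        seed = childSeed(seed, 1L))
  tau <- feedbackDelay(map)
  gap <- trace@support + tau
  cd <- config$code
  code <- if (cd$kind == "variable")
    generateVariableCode(cd$nNeurons, cd$renditionsPerEpoch,
                         cd$renditionLen, cd$t0, cd$dt, cd$burstRate,
                         gap = gap, seed = childSeed(seed, 2L))
  else
    generateStereotypedCode(cd$nNeurons, 1L, cd$interBurstLag, cd$t0,
                            cd$dt, cycles = cd$cycles, gap = gap,
                            seed = childSeed(seed, 2L))
  timings$generate <- tic() - t1
  log("generate: %s code, %d neurons, %d rendition(s) [%.2fs]", cd$kind,
      cd$nNeurons, length(renditions(code)), timings$generate)

  t1 <- tic()
  lr <- config$learning
  run <- runMirroringExperiment(code, map, trace, nEpochs = lr$nEpochs,
                                rateScale = lr$rateScale,
                                convergenceTol = lr$convergenceTol,
                                tailFrac = lr$tailFrac,
                                maxLag = config$mirroring$maxLag,
                                nNull = config$mirroring$nNull,
                                seed = childSeed(seed, 3L))
  timings$learn_mirror <- tic() - t1
  d <- run$weights@diagnostics
  log("learn: %d epochs, eta = %.3g, final rel. update %.3g [%.2fs]",
      d$epochs, d$learningRate, d$finalRelUpdate, timings$learn_mirror)

  ## closed-form agreement
  Vl <- weightMatrix(run$weights)
  predC <- predictedCausalInverse(map, trace, cd$t0)
  errC <- relFrobenius(Vl, predC)
  errP <- NA_real_
  if (cd$kind == "stereotyped") {
    sh <- try(shifterFromCode(code, tau), silent = TRUE)
    if (!inherits(sh, "try-error"))
      errP <- relFrobenius(Vl, predictedPredictiveInverse(map, trace,
                                                          cd$t0, sh))
  }

  offs <- offsets(run$result)
  med <- stats::median(offs, na.rm = TRUE)
  verdict <- if (abs(med - tau) <= cd$t0 / 2) "causal"
             else if (abs(med) <= cd$t0) "predictive"
             else "ambiguous"
  report <- list(
    config = unclass(config), tau = tau,
    offsets_ms = offs, offset_median_ms = med,
    peak_values = peakValues(run$result),
    gains = mirrorGains(run$result),
    mean_gain = mean(mirrorGains(run$result), na.rm = TRUE),
    causal_inverse_rel_error = errC,
    predictive_inverse_rel_error = errP,
    dichotomy_verdict = verdict,
    learning = d[c("epochs", "learningRate", "converged",
                   "finalRelUpdate")],
    timings = timings)
  log("verdict: %s inverse (median offset %g ms, tau = %g ms)", verdict,
      med, tau)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeWeights(run$weights, file.path(outDir, "weights.csv"))
    writeCorrelogram(run$result@corr, file.path(outDir, "correlograms.csv"))
    write.csv(data.frame(neuron = seq_along(offs), offset_ms = offs,
                         peak_value = peakValues(run$result),
                         gain = mirrorGains(run$result)),
              file.path(outDir, "offsets.csv"), row.names = FALSE)
    writeMap(map, file.path(outDir, "map.csv"))
    write_json(report, file.path(outDir, "report.json"),
               auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  }
  invisible(report)
}
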