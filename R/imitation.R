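#' Construct a syllable alphabet
#'
#' Realizes discrete syllables as orthogonal one-hot motor population
#' vectors (the simplest linearly independent patterns) together with their
#' sensory images under the feedback map.
#'
#' @param labels character vector of syllable labels; one motor neuron per
#'   label.
#' @param map a \linkS4class{MotorSensoryMap} with as many motor columns as
#'   labels.
#' @param t0 syllable slot width in ms.
#' @param dt bin width in ms.
#' @return a \linkS4class{SyllableAlphabet}.
#' @export
syllableAlphabet <- function(labels, map, t0 = 10, dt = 1) {
  n <- length(labels)
  if (ncol(map@Q) != n)
    stop("map must have one motor dimension per syllable")
  M <- diag(n)
  new("SyllableAlphabet", labels = labels, motorPatterns = M,
      sensoryPatterns = map@Q %*% M, t0 = t0, dt = dt)
}

#' Build a sensory target stream from syllable labels
#'
#' Lays the labels' sensory patterns out in non-overlapping slots of width
#' t0 whose onsets are spaced by \code{slotSpacing}.
#'
#' @param alphabet a \linkS4class{SyllableAlphabet}.
#' @param labelSeq character vector of labels to concatenate.
#' @param slotSpacing onset-to-onset spacing in ms (>= t0).
#' @return sensory rate matrix with an \code{"onsets"} attribute (bin
#'   indices of the slot onsets).
#' @export
buildSensoryTarget <- function(alphabet, labelSeq, slotSpacing = NULL) {
  dt <- alphabet@dt
  t0b <- msToBins(alphabet@t0, dt, "t0")
  if (is.null(slotSpacing)) slotSpacing <- alphabet@t0
  spb <- msToBins(slotSpacing, dt, "slotSpacing")
  stopifnot(spb >= t0b)
  k <- match(labelSeq, alphabet@labels)
  if (anyNA(k)) stop("unknown label(s): ",
                     paste(labelSeq[is.na(k)], collapse = ", "))
  T <- (length(k) - 1L) * spb + t0b
  a <- matrix(0, nrow(alphabet@sensoryPatterns), T)
  on <- (seq_along(k) - 1L) * spb + 1L
  for (s in seq_along(k))
    a[, on[s] + 0:(t0b - 1L)] <- alphabet@sensoryPatterns[, k[s]]
  attr(a, "onsets") <- on
  a
}

#' Feedforward imitation of a sensory target
#'
#' Computes the motor command stream for a desired sensory sequence through
#' the learned inverse model, \eqn{m^a(t) = V a(t)} per bin.  Requires an
#' open gate (the quiet, non-singing state).
#'
#' @param V a \linkS4class{SynapticWeights} with \code{gated(V) = FALSE}.
#' @param targetSensory sensory rate matrix (sensory x T).
#' @return motor stream (motor x T); onsets attribute is propagated.
#' @export
imitate <- function(V, targetSensory) {
  out <- playbackResponse(V, targetSensory)
  attr(out, "onsets") <- attr(targetSensory, "onsets")
  out
}

#' Decode a motor stream into syllable labels
#'
#' Per syllable slot, averages the motor population vector over the slot
#' window and classifies it by cosine similarity against the alphabet's
#' motor patterns; slots whose best similarity is below the threshold decode
#' to \code{NA} (no coherent syllable).
#'
#' @param motorStream motor rate matrix; slot onsets taken from its
#'   \code{"onsets"} attribute unless given.
#' @param alphabet a \linkS4class{SyllableAlphabet}.
#' @param onsets slot onset bins.
#' @param threshold minimum cosine similarity.
#' @return character vector of labels (NA for null slots).
#' @export
decodeSyllables <- function(motorStream, alphabet, onsets = NULL,
                            threshold = 0.5) {
  if (is.null(onsets)) onsets <- attr(motorStream, "onsets")
  if (is.null(onsets)) stop("slot onsets are required")
  t0b <- msToBins(alphabet@t0, alphabet@dt, "t0")
  vapply(onsets, function(o) {
    v <- rowMeans(motorStream[, o + 0:(t0b - 1L), drop = FALSE])
    decodeVector(v, alphabet, threshold)
  }, character(1))
}

# Cosine-similarity classification of a single population vector.
decodeVector <- function(v, alphabet, threshold = 0.5) {
  nv <- sqrt(sum(v^2))
  if (nv < .Machine$double.eps^0.5) return(NA_character_)
  P <- alphabet@motorPatterns
  sims <- as.vector(crossprod(P, v)) / (nv * sqrt(colSums(P^2)))
  if (max(sims) < threshold) return(NA_character_)
  alphabet@labels[which.max(sims)]
}

#' The ABCD / ABDB imitation demonstration
#'
#' Self-contained demo of why predictive inverses are poor imitators.  A
#' four-syllable alphabet (A, B, C, D) is produced either as a repeated
#' stereotyped cycle ABCD (inter-syllable lag equal to the loop delay, so
#' the learned shifter advances exactly one syllable) or as a variable code,
#' and the inverse model is learned in each regime.  Imitation of the target
#' ABDB is then attempted:
#' \itemize{
#'   \item causal inverse (variable training): open-loop imitation
#'     reproduces the target, ABDB — arbitrary resequencing of the learned
#'     repertoire works.
#'   \item predictive inverse (stereotyped training): each percept maps to
#'     its training successor, so once production starts the bird's own
#'     feedback locks it into the shifted training cycle: starting from the
#'     percept A it produces repetitions of BCDA, regardless of the target.
#'     The open-loop slot-by-slot mapping (each target percept to its
#'     successor) is also reported.
#' }
#'
#' @param seed integer seed (map draw and variable-code exploration).
#' @param nSlots length of the closed-loop production to report.
#' @return list with the training sequence, target, decoded productions and
#'   match flags.
#' @export
abcdDemo <- function(seed = 1L, nSlots = 4L) {
  labels <- c("A", "B", "C", "D")
  tauM <- 25; tauA <- 15; tau <- tauM + tauA
  t0 <- 10; dt <- 1
  map <- randomInvertibleMap(4, 4, tauM = tauM, tauA = tauA,
                             conditionCap = 5, seed = seed)
  # steep-trace regime (decay < tau / ln 2): the learned association from a
  # percept to its training successor then dominates the self association,
  # which is what the successor-mapping argument presumes (the zero-lag
  # correlation tooth only carries half its mass; see the methods vignette)
  trace <- eligibilityTrace("exponential", decayTime = 30)
  alphabet <- syllableAlphabet(labels, map, t0 = t0, dt = dt)
  gap <- trace@support + tau
  target <- c("A", "B", "D", "B")

  ## predictive regime: repeated ABCD cycles, inter-syllable lag = tau
  codeS <- generateStereotypedCode(4, 1, interBurstLag = tau, t0 = t0,
                                   dt = dt, cycles = 4L,
                                   renditionLen = 4 * 4 * tau + t0,
                                   gap = gap)
  Vs <- suppressWarnings(
    runLearning(synapticWeights(nMotor = 4, nSensory = 4), codeS, map,
                trace, nEpochs = 300L, convergenceTol = 0, seed = seed,
                tailFrac = 0.1))
  gated(Vs) <- FALSE

  ## causal regime: variable exploration over the same syllable repertoire
  codeV <- generateVariableCode(4, 20, renditionLen = 8000, t0 = t0,
                                dt = dt, gap = gap, seed = seed)
  Vc <- suppressWarnings(
    runLearning(synapticWeights(nMotor = 4, nSensory = 4), codeV, map,
                trace, nEpochs = 50L, seed = seed))
  gated(Vc) <- FALSE

  ## causal, open loop: track the external target
  aT <- buildSensoryTarget(alphabet, target, slotSpacing = tau)
  causal <- decodeSyllables(imitate(Vc, aT), alphabet)

  ## predictive, open loop: every percept maps to its training successor
  predictiveOpen <- decodeSyllables(imitate(Vs, aT), alphabet)

  ## predictive, closed loop: production seeded by the target's first
  ## percept, then driven by the bird's own feedback
  percept <- target[1L]
  produced <- character(nSlots)
  for (k in seq_len(nSlots)) {
    v <- as.vector(Vs@V %*% alphabet@sensoryPatterns[, match(percept,
                                                             labels)])
    produced[k] <- decodeVector(v, alphabet)
    if (is.na(produced[k])) break
    percept <- produced[k]
  }

  succ <- labels[c(2, 3, 4, 1)]  # training successor of each label
  list(trainedOn = "ABCD", target = paste(target, collapse = ""),
       causalProduced = paste(causal, collapse = ""),
       predictiveProduced = paste(produced, collapse = ""),
       predictiveOpenLoop = paste(predictiveOpen, collapse = ""),
       matchesPaper = identical(paste(produced, collapse = ""), "BCDA") &&
                      identical(causal, target),
       successorMap = setNames(succ, labels))
}

setMethod("show", "SyllableAlphabet", function(object) {
  cat(sprintf("SyllableAlphabet: %s (slot width %g ms)\n",
              paste(object@labels, collapse = ""), object@t0))
})
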