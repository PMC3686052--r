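#' @importClassesFrom IRanges IRanges
#' @importFrom IRanges IRanges start end width
NULL

#' MotorCode: a population motor rate code
#'
#' Rates of \code{N_m} motor neurons on a uniform time grid, organised into
#' renditions (repetitions of a song motif or babbling bout) separated by
#' silent gaps.  Activity consists of square bursts of width \code{t0} and
#' unit amplitude.  The object also records the generator and its parameters
#' so that statistically fresh renditions can be drawn during learning.
#'
#' @slot rates non-negative numeric matrix, neurons x time bins.
#' @slot dt bin width in ms.
#' @slot t0 burst width in ms.
#' @slot renditions \code{IRanges} of rendition spans (bin indices).
#' @slot codeKind \code{"variable"} or \code{"stereotyped"}.
#' @slot params list of generator parameters (including the seed).
#'
#' @name MotorCode-class
#' @aliases MotorCode
#' @exportClass MotorCode
setClass("MotorCode",
  representation(
    rates = "matrix",
    dt = "numeric",
    t0 = "numeric",
    renditions = "IRanges",
    codeKind = "character",
    params = "list"
  )
)

setValidity("MotorCode", function(object) {
  msg <- character()
  if (any(!is.finite(object@rates)) || any(object@rates < 0))
    msg <- c(msg, "rates must be finite and non-negative")
  if (length(object@dt) != 1L || object@dt <= 0)
    msg <- c(msg, "dt must be a single positive number")
  if (object@t0 < object@dt)
    msg <- c(msg, "burst width t0 must be at least one bin")
  if (!object@codeKind %in% c("variable", "stereotyped"))
    msg <- c(msg, "codeKind must be 'variable' or 'stereotyped'")
  r <- object@renditions
  if (length(r)) {
    if (is.unsorted(start(r), strictly = FALSE))
      msg <- c(msg, "renditions must be ordered")
    if (length(r) > 1L && any(start(r)[-1L] <= end(r)[-length(r)]))
      msg <- c(msg, "renditions must not overlap")
    if (max(end(r)) > ncol(object@rates))
      msg <- c(msg, "renditions exceed the time axis")
  }
  if (length(msg)) msg else TRUE
})

#' MotorSensoryMap: delayed linear motor-to-sensory feedback
#'
#' The composite pathway from motor activity to sensory response, modelled as
#' one linear map \code{Q} applied with loop delay \code{tau = tauM + tauA}:
#' \code{a(t) = Q m(t - tau)}.  \code{tauM} is the motor-to-behaviour delay
#' and \code{tauA} the behaviour-to-sensory delay; only their sum enters the
#' dynamics, both are kept for experiment bookkeeping.
#'
#' @slot Q numeric matrix, sensory x motor.
#' @slot tauM,tauA delays in ms, both non-negative.
#' @slot rank column rank of Q, recorded at construction.
#'
#' @name MotorSensoryMap-class
#' @aliases MotorSensoryMap
#' @exportClass MotorSensoryMap
setClass("MotorSensoryMap",
  representation(Q = "matrix", tauM = "numeric", tauA = "numeric",
                 rank = "integer")
)

setValidity("MotorSensoryMap", function(object) {
  msg <- character()
  if (any(!is.finite(object@Q))) msg <- c(msg, "Q must be finite")
  if (object@tauM < 0 || object@tauA < 0)
    msg <- c(msg, "delays must be non-negative")
  if (object@rank > min(dim(object@Q)))
    msg <- c(msg, "rank cannot exceed min(dim(Q))")
  if (length(msg)) msg else TRUE
})

#' EligibilityTrace: postsynaptic eligibility window
#'
#' A non-negative gain \code{e(s)} on \code{s >= 0} that makes synapses onto a
#' recently active motor neuron modifiable, bridging the feedback delay.
#' Monotone non-increasing for the built-in kinds; arbitrary sampled tables
#' are allowed only with \code{nonMonotone = TRUE}.
#'
#' @slot kind \code{"exponential"}, \code{"linear_decay"} or
#'   \code{"custom_table"}.
#' @slot e0 value at s = 0 (dimensionless gain).
#' @slot decayTime decay time constant (exponential) or time-to-zero
#'   (linear) in ms.
#' @slot support truncation horizon in ms; e(s) = 0 beyond it.
#' @slot table sampled values on a dt grid (custom kind), else empty.
#' @slot tableDt grid step of \code{table} in ms.
#' @slot nonMonotone whether a non-monotone custom table was allowed.
#'
#' @name EligibilityTrace-class
#' @aliases EligibilityTrace
#' @exportClass EligibilityTrace
setClass("EligibilityTrace",
  representation(kind = "character", e0 = "numeric", decayTime = "numeric",
                 support = "numeric", table = "numeric", tableDt = "numeric",
                 nonMonotone = "logical")
)

setValidity("EligibilityTrace", function(object) {
  msg <- character()
  if (!object@kind %in% c("exponential", "linear_decay", "custom_table"))
    msg <- c(msg, "unknown trace kind")
  if (object@e0 < 0) msg <- c(msg, "e0 must be non-negative")
  if (object@support <= 0) msg <- c(msg, "support must be positive")
  if (object@kind != "custom_table" && object@decayTime <= 0)
    msg <- c(msg, "decayTime must be positive")
  if (object@kind == "custom_table") {
    if (!length(object@table)) msg <- c(msg, "custom_table needs a table")
    if (any(object@table < 0)) msg <- c(msg, "eligibility must be >= 0")
    if (!object@nonMonotone && length(object@table) > 1L &&
        any(diff(object@table) > 1e-12))
      msg <- c(msg, "table not monotone non-increasing (set nonMonotone = TRUE to allow)")
  }
  if (length(msg)) msg else TRUE
})

#' SynapticWeights: the learned sensory-to-motor map
#'
#' Weight matrix \code{V} (motor x sensory).  While \code{gated} is TRUE the
#' weights only correlate pre- and postsynaptic activity "silently" and must
#' not drive motor responses; playback responses require an open gate.
#'
#' @slot V numeric matrix, motor x sensory.
#' @slot learningRate step scale actually used (filled by the learning run).
#' @slot gated whether sensory input is gated out of the motor area.
#' @slot diagnostics list of convergence diagnostics (update-norm trajectory,
#'   epochs run, learning rate, convergence flag).
#'
#' @name SynapticWeights-class
#' @aliases SynapticWeights
#' @exportClass SynapticWeights
setClass("SynapticWeights",
  representation(V = "matrix", learningRate = "numeric", gated = "logical",
                 diagnostics = "list")
)

setValidity("SynapticWeights", function(object) {
  if (any(!is.finite(object@V))) "V must be finite (divergence?)" else TRUE
})

#' ShifterMatrix: time-advance operator of a stereotyped code
#'
#' For a traveling-pulse code, maps the motor population state at time t to
#' the state at t + tau: a neuron-index shift.  Rows have at most one
#' non-zero entry.
#'
#' @slot H numeric matrix, motor x motor.
#' @slot tau the advance in ms the shifter realises.
#'
#' @name ShifterMatrix-class
#' @aliases ShifterMatrix
#' @exportClass ShifterMatrix
setClass("ShifterMatrix", representation(H = "matrix", tau = "numeric"))

setValidity("ShifterMatrix", function(object) {
  if (any(rowSums(object@H != 0) > 1L))
    "rows of a pure traveling-pulse shifter have at most one non-zero entry"
  else TRUE
})

#' CrossCorrelation: cross-correlogram container
#'
#' Lagged second-order statistics between two rate signals.  The sign
#' convention throughout the package: \code{C[i, j, s]} correlates
#' \code{a_i(t)} with \code{b_j(t + s)}, so a positive lag means signal b
#' lags signal a.
#'
#' @slot lags lag values in ms, symmetric about 0.
#' @slot values array (units a) x (units b) x lag.
#' @slot normalization \code{"raw_covariance"} or \code{"pearson"}.
#' @slot dt bin width in ms.
#'
#' @name CrossCorrelation-class
#' @aliases CrossCorrelation
#' @exportClass CrossCorrelation
setClass("CrossCorrelation",
  representation(lags = "numeric", values = "array",
                 normalization = "character", dt = "numeric")
)

setValidity("CrossCorrelation", function(object) {
  msg <- character()
  if (!object@normalization %in% c("raw_covariance", "pearson"))
    msg <- c(msg, "unknown normalization")
  if (dim(object@values)[3L] != length(object@lags))
    msg <- c(msg, "lag axis mismatch")
  if (length(msg)) msg else TRUE
})

#' MirroringResult: outcome of an in-silico mirroring experiment
#'
#' Per-neuron comparison of motor activity during production with the
#' sensory-evoked (playback) response driven through the learned weights.
#'
#' @slot corr \code{CrossCorrelation} (Pearson) of motor vs playback response.
#' @slot offsets per-neuron mirroring offset in ms (lag of peak correlation).
#' @slot peakValues per-neuron peak Pearson correlation.
#' @slot gains per-neuron mirroring gain: peak raw cross-covariance divided by
#'   the motor auto-covariance peak; the observable behind the peak-ratio law.
#' @slot flat logical per neuron: peak indistinguishable from the shuffle
#'   null (only filled when a null was requested).
#' @slot config list identifying the run (map digest, tau, trace, t0) so that
#'   ratios are only formed across matched experiments.
#'
#' @name MirroringResult-class
#' @aliases MirroringResult
#' @exportClass MirroringResult
setClass("MirroringResult",
  representation(corr = "CrossCorrelation", offsets = "numeric",
                 peakValues = "numeric", gains = "numeric", flat = "logical",
                 config = "list")
)

#' BinaryMirrorChannel: two-state probabilistic mirroring model
#'
#' Binary motor state M (prior \code{pM1}) and binary sensory detection S,
#' coupled by the tuning probabilities \code{p(S=1|M=1)} and
#' \code{p(S=1|M=0)}, with optional independent symmetric flip noise on each
#' variable modelling intrinsic motor and sensory noise.
#'
#' @slot pM1 prior probability of M = 1.
#' @slot pS1gM1,pS1gM0 detection probabilities given the motor state.
#' @slot motorNoise,sensorNoise symmetric flip probabilities in [0, 1/2].
#'
#' @name BinaryMirrorChannel-class
#' @aliases BinaryMirrorChannel
#' @exportClass BinaryMirrorChannel
setClass("BinaryMirrorChannel",
  representation(pM1 = "numeric", pS1gM1 = "numeric", pS1gM0 = "numeric",
                 motorNoise = "numeric", sensorNoise = "numeric")
)

setValidity("BinaryMirrorChannel", function(object) {
  p <- c(object@pM1, object@pS1gM1, object@pS1gM0)
  nz <- c(object@motorNoise, object@sensorNoise)
  msg <- character()
  if (any(p < 0 | p > 1)) msg <- c(msg, "probabilities must lie in [0, 1]")
  if (any(nz < 0 | nz > 0.5)) msg <- c(msg, "flip noise must lie in [0, 1/2]")
  if (length(msg)) msg else TRUE
})

#' SyllableAlphabet: labelled motor/sensory syllable patterns
#'
#' Orthogonal one-hot motor population vectors, one per syllable label, and
#' their sensory images under a motor-sensory map.  Used by the imitation
#' demos to read motor streams back into label sequences.
#'
#' @slot labels character vector of syllable labels.
#' @slot motorPatterns matrix, motor dim x syllables.
#' @slot sensoryPatterns matrix, sensory dim x syllables (Q motorPatterns).
#' @slot t0 syllable slot width in ms.
#' @slot dt bin width in ms.
#'
#' @name SyllableAlphabet-class
#' @aliases SyllableAlphabet
#' @exportClass SyllableAlphabet
setClass("SyllableAlphabet",
  representation(labels = "character", motorPatterns = "matrix",
                 sensoryPatterns = "matrix", t0 = "numeric", dt = "numeric")
)

setValidity("SyllableAlphabet", function(object) {
  if (ncol(object@motorPatterns) != length(object@labels))
    return("one motor pattern per label required")
  if (qr(object@motorPatterns)$rank < length(object@labels))
    return("motor patterns must be linearly independent")
  TRUE
})
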