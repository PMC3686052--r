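#' Generate a variable (uncorrelated) motor code
#'
#' Emulates an explorative motor code such as LMAN firing during babbling:
#' in every rendition each neuron emits square bursts of width \code{t0} and
#' unit amplitude at independently, uniformly random onsets.  Across neurons
#' the expected cross-correlation is flat; the auto-correlation has a single
#' peak of width ~\code{t0} at zero lag (white-noise idealisation).
#'
#' The default rendition is a long (8 s) bout with one burst per neuron, i.e.
#' a sparse code.  Sparseness matters: the white-noise idealisation behind
#' the causal-inverse prediction holds up to corrections of order
#' (burst density) x (eligibility mass), so dense codes bias the learned
#' weights along the population-mean direction (see the methods vignette).
#'
#' @param nNeurons number of motor neurons.
#' @param nRenditions number of renditions.
#' @param renditionLen rendition length in ms.
#' @param t0 burst width in ms.
#' @param dt bin width in ms.
#' @param burstRate integer bursts per neuron per rendition.
#' @param gap silent gap between renditions in ms.  Learning experiments use
#'   a gap of at least the feedback delay plus the eligibility support so no
#'   correlations straddle rendition boundaries.
#' @param seed integer seed; the code is reproducible from its parameters.
#' @return a \linkS4class{MotorCode}.
#' @export
#' @examples
#' code <- generateVariableCode(4, 10, renditionLen = 500, seed = 1)
#' code
generateVariableCode <- function(nNeurons, nRenditions, renditionLen = 8000,
                                 t0 = 10, dt = 1, burstRate = 1L, gap = 0,
                                 seed = 1L) {
  if (t0 < dt) stop("invalid parameter: t0 < dt")
  if (renditionLen < 2 * t0)
    stop("invalid parameter: renditionLen < 2 * t0")
  t0b <- msToBins(t0, dt, "t0")
  Lb <- msToBins(renditionLen, dt, "renditionLen")
  gapb <- msToBins(gap, dt, "gap")
  burstRate <- as.integer(burstRate)
  stopifnot(burstRate >= 1L)

  T <- nRenditions * (Lb + gapb)
  rates <- matrix(0, nNeurons, T)
  starts <- (seq_len(nRenditions) - 1L) * (Lb + gapb) + 1L
  withSeed(seed, {
    for (r in seq_len(nRenditions)) {
      off <- starts[r] - 1L
      for (i in seq_len(nNeurons)) {
        on <- sample.int(Lb - t0b + 1L, burstRate, replace = TRUE) - 1L
        for (o in on) rates[i, off + o + seq_len(t0b)] <- 1
      }
    }
  })
  new("MotorCode", rates = rates, dt = dt, t0 = t0,
      renditions = IRanges(start = starts, width = Lb),
      codeKind = "variable",
      params = list(generator = "variable", nNeurons = nNeurons,
                    nRenditions = nRenditions, renditionLen = renditionLen,
                    t0 = t0, dt = dt, burstRate = burstRate, gap = gap,
                    seed = seed))
}

#' Generate a stereotyped (traveling-pulse) motor code
#'
#' Emulates a stereotyped premotor sequence such as HVC firing during adult
#' song: in every rendition neuron i bursts at the fixed onset
#' \code{(i - 1) * interBurstLag}, so pairwise cross-correlations peak at
#' non-zero lags set by the neurons' positions in the sequence.  With
#' \code{cycles > 1} the pulse train repeats cyclically within a rendition
#' (period \code{nNeurons * interBurstLag}), which makes the sequence wrap
#' around as in continuously repeated song.
#'
#' @inheritParams generateVariableCode
#' @param interBurstLag lag between consecutive neurons' burst onsets, ms.
#' @param cycles repetitions of the full pulse train per rendition.
#' @param renditionLen rendition length in ms; defaults to the exact length
#'   of the pulse train.
#' @return a \linkS4class{MotorCode}.
#' @export
#' @examples
#' code <- generateStereotypedCode(4, 3, interBurstLag = 20)
generateStereotypedCode <- function(nNeurons, nRenditions, interBurstLag,
                                    t0 = 10, dt = 1, cycles = 1L,
                                    renditionLen = NULL, gap = 0,
                                    seed = 1L) {
  if (t0 < dt) stop("invalid parameter: t0 < dt")
  if (interBurstLag < 0) stop("invalid parameter: interBurstLag < 0")
  t0b <- msToBins(t0, dt, "t0")
  lagb <- msToBins(interBurstLag, dt, "interBurstLag")
  cycles <- as.integer(cycles)
  period <- nNeurons * lagb
  trainLen <- (cycles - 1L) * period + (nNeurons - 1L) * lagb + t0b
  if (is.null(renditionLen)) renditionLen <- trainLen * dt
  Lb <- msToBins(renditionLen, dt, "renditionLen")
  gapb <- msToBins(gap, dt, "gap")
  if (trainLen > Lb)
    stop("invalid parameter: pulse train does not fit in a rendition")

  onsets <- outer((seq_len(nNeurons) - 1L) * lagb,
                  (seq_len(cycles) - 1L) * period, "+")  # neurons x cycles
  T <- nRenditions * (Lb + gapb)
  rates <- matrix(0, nNeurons, T)
  starts <- (seq_len(nRenditions) - 1L) * (Lb + gapb) + 1L
  for (r in seq_len(nRenditions)) {
    off <- starts[r] - 1L
    for (i in seq_len(nNeurons))
      for (o in onsets[i, ]) rates[i, off + o + seq_len(t0b)] <- 1
  }
  new("MotorCode", rates = rates, dt = dt, t0 = t0,
      renditions = IRanges(start = starts, width = Lb),
      codeKind = "stereotyped",
      params = list(generator = "stereotyped", nNeurons = nNeurons,
                    nRenditions = nRenditions, interBurstLag = interBurstLag,
                    t0 = t0, dt = dt, cycles = cycles,
                    renditionLen = renditionLen, gap = gap, seed = seed,
                    onsetsMs = onsets * dt))
}

# Fresh renditions with the same statistics (variable codes only; a
# stereotyped code is identical from rendition to rendition).
regenerateCode <- function(code, seed) {
  p <- code@params
  if (code@codeKind != "variable") return(code)
  generateVariableCode(p$nNeurons, p$nRenditions, p$renditionLen, p$t0,
                       p$dt, p$burstRate, p$gap, seed = seed)
}

#' Cross-correlation functions between rate signals
#'
#' Computes lagged second-order statistics C_ij(s) between all unit pairs of
#' two rate matrices on a common time base.  Convention: \code{C[i, j, s]}
#' correlates \code{a_i(t)} with \code{b_j(t + s)}; a positive lag means b
#' lags a.  \code{raw_covariance} subtracts each signal's mean over the full
#' analysis window and averages products over the overlapping bins;
#' \code{pearson} additionally divides by the product of the signals'
#' standard deviations.  Constant signals under \code{pearson} yield
#' \code{NA} (undefined correlation) with a warning rather than a division
#' by zero.
#'
#' @param codeA,codeB \linkS4class{MotorCode} objects or numeric matrices
#'   (units x time) on the same time base.
#' @param maxLag largest lag magnitude in ms.
#' @param normalization \code{"raw_covariance"} or \code{"pearson"}.
#' @param dt bin width in ms (taken from the codes when omitted).
#' @return a \linkS4class{CrossCorrelation}.
#' @export
#' @examples
#' x <- matrix(sin(1:200 / 5), 1)
#' cc <- crossCorrelation(x, x, maxLag = 20, normalization = "pearson", dt = 1)
#' lags(cc)[which.max(corValues(cc)[1, 1, ])]  # 0
crossCorrelation <- function(codeA, codeB, maxLag,
                             normalization = c("raw_covariance", "pearson"),
                             dt = NULL) {
  normalization <- match.arg(normalization)
  getm <- function(x) if (is(x, "MotorCode")) x@rates else as.matrix(x)
  getdt <- function(x) if (is(x, "MotorCode")) x@dt else NULL
  A <- getm(codeA); B <- getm(codeB)
  dts <- c(getdt(codeA), getdt(codeB), dt)
  if (!length(dts)) stop("dt must be given for plain matrices")
  if (length(unique(dts)) != 1L) stop("time bases differ (dt mismatch)")
  dt <- dts[1L]
  if (ncol(A) != ncol(B)) stop("signals must share the time base")
  T <- ncol(A)
  maxLagB <- msToBins(maxLag, dt, "maxLag")
  if (maxLagB >= T) stop("maxLag must be shorter than the segment")

  Am <- A - rowMeans(A)
  Bm <- B - rowMeans(B)
  lagsB <- (-maxLagB):maxLagB
  vals <- array(NA_real_, c(nrow(A), nrow(B), length(lagsB)))
  for (k in seq_along(lagsB)) {
    s <- lagsB[k]
    if (s >= 0) {
      ia <- seq_len(T - s); ib <- ia + s
    } else {
      ib <- seq_len(T + s); ia <- ib - s
    }
    vals[, , k] <- tcrossprod(Am[, ia, drop = FALSE],
                              Bm[, ib, drop = FALSE]) / length(ia)
  }
  if (normalization == "pearson") {
    sa <- sqrt(rowMeans(Am^2)); sb <- sqrt(rowMeans(Bm^2))
    bad <- outer(sa == 0, sb == 0, "|")
    den <- outer(sa, sb)
    den[bad] <- NA_real_
    if (any(bad))
      warning("constant signal(s): undefined correlation marked NA")
    vals <- sweep(vals, c(1, 2), den, "/")
  }
  new("CrossCorrelation", lags = lagsB * dt, values = vals,
      normalization = normalization, dt = dt)
}

# Peak lag of a single correlogram vector; ties broken towards the smallest
# |lag|, then towards the negative lag.
peakLag <- function(lags, v, tol = 1e-12) {
  m <- max(v, na.rm = TRUE)
  cand <- which(v >= m - tol)
  cand <- cand[order(abs(lags[cand]), lags[cand])]
  cand[1L]
}

## ---- accessors & show ----

#' @rdname accessors
#' @export
setMethod("rates", "MotorCode", function(x) x@rates)

#' @rdname accessors
#' @export
setMethod("binWidth", "MotorCode", function(x) x@dt)

#' @rdname accessors
#' @export
setMethod("burstWidth", "MotorCode", function(x) x@t0)

#' @rdname accessors
#' @export
setMethod("renditions", "MotorCode", function(x) x@renditions)

#' @rdname accessors
#' @export
setMethod("codeKind", "MotorCode", function(x) x@codeKind)

#' @rdname accessors
#' @export
setMethod("lags", "CrossCorrelation", function(x) x@lags)

#' @rdname accessors
#' @export
setMethod("corValues", "CrossCorrelation", function(x) x@values)

setMethod("show", "MotorCode", function(object) {
  cat(sprintf("MotorCode (%s): %d neurons x %d bins (dt = %g ms)\n",
              object@codeKind, nrow(object@rates), ncol(object@rates),
              object@dt))
  cat(sprintf("  %d renditions, burst width t0 = %g ms\n",
              length(object@renditions), object@t0))
})

setMethod("show", "CrossCorrelation", function(object) {
  d <- dim(object@values)
  cat(sprintf("CrossCorrelation (%s): %d x %d pairs, lags %g..%g ms\n",
              object@normalization, d[1], d[2], min(object@lags),
              max(object@lags)))
})
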