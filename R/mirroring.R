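#' Sensory-evoked (playback) motor response
#'
#' In the playback state (bird asleep / anaesthetised, auditory gate open)
#' sensory responses drive motor neurons through the learned weights:
#' \eqn{m^a(t) = V a(t)}, instantaneous (no synaptic delay between sensory
#' and motor neurons).  Refuses to run on gated weights: during learning the
#' weights are silent by construction, so the learning loop can never evoke
#' playback responses.
#'
#' @param V a \linkS4class{SynapticWeights} with an open gate
#'   (\code{gated(V) <- FALSE}).
#' @param sensory rate matrix (sensory x T).
#' @return motor response matrix (motor x T).
#' @export
playbackResponse <- function(V, sensory) {
  if (gated(V))
    stop("gate is closed: playback responses require gated(V) <- FALSE ",
         "(weights are silent during learning)")
  if (ncol(V@V) != nrow(sensory))
    stop("dimension mismatch between V and the sensory stream")
  V@V %*% sensory
}

#' Mirroring offsets from motor and playback activity
#'
#' For every neuron, cross-correlates its motor activity m_i(t) during
#' production with its playback response m^a_i(t) and reports the lag of
#' peak correlation — the mirroring offset.  A converged causal inverse
#' yields offsets near the loop delay tau (the playback response lags the
#' motor command by one trip around the loop); a predictive inverse yields
#' offsets near zero (sensory feedback from past actions maps onto currently
#' active motor neurons).  Offsets use Pearson normalization; the slot
#' \code{gains} additionally stores each neuron's peak raw cross-covariance
#' divided by its motor auto-covariance peak, the amplitude observable whose
#' variable/stereotyped ratio follows the eligibility trace (see
#' \code{\link{peakRatio}}).
#'
#' Ties at the peak break towards the smallest |lag|, then the negative lag.
#' With \code{nNull > 0} a shuffle null (playback circularly shifted within
#' each rendition, \code{nNull} times) flags neurons whose peak does not
#' exceed the null's \code{nullQuantile}.
#'
#' @param motor a \linkS4class{MotorCode} (or rate matrix) recorded during
#'   production.
#' @param playback playback response matrix, same time base (song-aligned).
#' @param maxLag correlogram half-width in ms.
#' @param dt bin width when \code{motor} is a plain matrix.
#' @param nNull shuffles for the flat-correlogram check (0 = skip).
#' @param nullQuantile quantile the true peak must exceed.
#' @param seed seed for the shuffle null.
#' @param config optional stamp (map digest, tau, trace, t0) enabling
#'   matched-run checks in \code{\link{peakRatio}}.
#' @return a \linkS4class{MirroringResult}.
#' @export
mirroringOffset <- function(motor, playback, maxLag = 100, dt = NULL,
                            nNull = 0L, nullQuantile = 0.95, seed = 1L,
                            config = list()) {
  m <- if (is(motor, "MotorCode")) motor@rates else as.matrix(motor)
  if (is(motor, "MotorCode")) dt <- motor@dt
  if (is.null(dt)) stop("dt must be given for plain matrices")
  if (!identical(dim(m)[2], dim(playback)[2]))
    stop("motor and playback must share the time base")
  n <- nrow(m)

  ccP <- crossCorrelation(m, playback, maxLag, "pearson", dt = dt)
  ccC <- crossCorrelation(m, playback, maxLag, "raw_covariance", dt = dt)
  lagv <- ccP@lags
  offs <- peaks <- gains <- numeric(n)
  C0 <- rowMeans((m - rowMeans(m))^2)   # motor auto-covariance peak
  for (i in seq_len(n)) {
    v <- ccP@values[i, i, ]
    if (all(is.na(v))) { offs[i] <- NA; peaks[i] <- NA; gains[i] <- NA; next }
    k <- peakLag(lagv, v)
    offs[i] <- lagv[k]
    peaks[i] <- v[k]
    gains[i] <- max(ccC@values[i, i, ]) / C0[i]
  }

  flat <- rep(NA, n)
  if (nNull > 0L) {
    rend <- if (is(motor, "MotorCode")) motor@renditions else NULL
    flat <- withSeed(seed, {
      nullPeaks <- matrix(NA_real_, nNull, n)
      for (b in seq_len(nNull)) {
        pb <- playback
        if (!is.null(rend) && length(rend)) {
          for (r in seq_along(rend)) {
            idx <- start(rend)[r]:end(rend)[r]
            sh <- sample.int(length(idx), 1L)
            pb[, idx] <- pb[, c(idx[-seq_len(sh)], idx[seq_len(sh)])]
          }
        } else {
          sh <- sample.int(ncol(pb), 1L)
          pb <- pb[, c((sh + 1):ncol(pb), 1:sh), drop = FALSE]
        }
        ccN <- crossCorrelation(m, pb, maxLag, "pearson", dt = dt)
        for (i in seq_len(n)) nullPeaks[b, i] <- max(ccN@values[i, i, ],
                                                     na.rm = TRUE)
      }
      sapply(seq_len(n), function(i) {
        q <- stats::quantile(nullPeaks[, i], nullQuantile, na.rm = TRUE)
        isTRUE(peaks[i] <= q)
      })
    })
    if (any(flat, na.rm = TRUE))
      warning("flat correlogram: peak within the shuffle null for neuron(s) ",
              paste(which(flat), collapse = ", "))
  }

  new("MirroringResult", corr = ccP, offsets = offs, peakValues = peaks,
      gains = gains, flat = flat, config = config)
}

#' Peak cross-correlation ratio between variable- and stereotyped-code runs
#'
#' The amplitude of mirrored responses differs between motor-code regimes:
#' for variable codes the playback response carries the eligibility at the
#' loop delay, e(tau), for stereotyped codes the eligibility near zero lag.
#' The ratio of peak amplitudes (variable / stereotyped) therefore tracks
#' e(tau)/e(0) — the steeper the trace, the weaker the mirrored response of
#' the variable-code circuit.  Amplitudes are compared through the
#' covariance gains (peak cross-covariance / motor auto-covariance peak),
#' which are invariant to burst density and, unlike Pearson coefficients,
#' retain the eligibility scale.
#'
#' @param resultVariable,resultStereotyped \linkS4class{MirroringResult}s
#'   from runs with identical map, delay, trace and burst width (enforced
#'   via their config stamps).
#' @return scalar ratio mean(gains variable) / mean(gains stereotyped).
#' @export
peakRatio <- function(resultVariable, resultStereotyped) {
  c1 <- resultVariable@config; c2 <- resultStereotyped@config
  keys <- c("mapDigest", "tau", "traceKind", "e0", "decayTime", "support",
            "t0")
  if (length(c1) && length(c2)) {
    for (k in intersect(keys, intersect(names(c1), names(c2))))
      if (!isTRUE(all.equal(c1[[k]], c2[[k]])))
        stop("config mismatch between runs: ", k, " differs")
  }
  mean(resultVariable@gains, na.rm = TRUE) /
    mean(resultStereotyped@gains, na.rm = TRUE)
}

#' Full in-silico mirroring experiment
#'
#' Learns the inverse model on the given code (gate closed), then replays
#' the sensory stream of the final learning epoch through the learned
#' weights with the gate open — "playback of the just recorded songs" — and
#' measures per-neuron mirroring offsets and gains.
#'
#' @param code epoch-template \linkS4class{MotorCode}.
#' @param map a \linkS4class{MotorSensoryMap}.
#' @param trace an \linkS4class{EligibilityTrace}.
#' @param nEpochs,rateScale,convergenceTol,tailFrac passed to
#'   \code{\link{runLearning}}.
#' @param maxLag correlogram half-width in ms.
#' @param nNull shuffles for the flat-correlogram check.
#' @param seed base seed.
#' @return list with elements \code{weights} (\linkS4class{SynapticWeights})
#'   and \code{result} (\linkS4class{MirroringResult}).
#' @export
runMirroringExperiment <- function(code, map, trace, nEpochs = 60L,
                                   rateScale = 0.5, convergenceTol = 1e-4,
                                   tailFrac = 0.3, maxLag = 100, nNull = 0L,
                                   seed = 1L) {
  V0 <- synapticWeights(nMotor = nrow(code@rates),
                        nSensory = nrow(map@Q), gated = TRUE)
  W <- runLearning(V0, code, map, trace, rateScale = rateScale,
                   nEpochs = nEpochs, convergenceTol = convergenceTol,
                   seed = seed, tailFrac = tailFrac)
  ep <- W@diagnostics$epochs
  codeLast <- if (ep == 1L) code else regenerateCode(code, childSeed(seed, ep))
  a <- sensoryResponse(map, codeLast)
  Wopen <- W
  gated(Wopen) <- FALSE
  ma <- playbackResponse(Wopen, a)
  cfg <- list(mapDigest = matrixDigest(map@Q), tau = feedbackDelay(map),
              traceKind = trace@kind, e0 = trace@e0,
              decayTime = trace@decayTime, support = trace@support,
              t0 = code@t0)
  res <- mirroringOffset(codeLast, ma, maxLag = maxLag, nNull = nNull,
                         seed = childSeed(seed, 999L), config = cfg)
  list(weights = W, result = res)
}

## ---- accessors & show ----

#' @rdname accessors
#' @export
setMethod("offsets", "MirroringResult", function(x) x@offsets)

#' @rdname accessors
#' @export
setMethod("peakValues", "MirroringResult", function(x) x@peakValues)

#' @rdname accessors
#' @export
setMethod("mirrorGains", "MirroringResult", function(x) x@gains)

setMethod("show", "MirroringResult", function(object) {
  cat(sprintf("MirroringResult: %d neurons\n", length(object@offsets)))
  cat("  offsets (ms): ", paste(object@offsets, collapse = ", "), "\n")
  cat(sprintf("  median offset %g ms; mean gain %.3g\n",
              stats::median(object@offsets, na.rm = TRUE),
              mean(object@gains, na.rm = TRUE)))
})
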