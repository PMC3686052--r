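#' Construct a synaptic weight object
#'
#' @param V initial weight matrix (motor x sensory), defaults to zeros.
#' @param nMotor,nSensory dimensions when \code{V} is not given.
#' @param gated whether the weights are gated out of the motor area (TRUE
#'   during learning: the weights correlate silently and do not drive motor
#'   activity).
#' @return a \linkS4class{SynapticWeights}.
#' @export
synapticWeights <- function(V = NULL, nMotor = NULL, nSensory = NULL,
                            gated = TRUE) {
  if (is.null(V)) V <- matrix(0, nMotor, nSensory)
  new("SynapticWeights", V = as.matrix(V), learningRate = NA_real_,
      gated = gated, diagnostics = list())
}

# Eligibility-filtered motor trace F(t) = sum_k kernel[k] m(t - (k-1) dt).
# Exploits the sparseness of burst codes: each non-zero motor bin scatters a
# copy of the kernel forward in time.
eligibilityFilter <- function(m, kernel) {
  T <- ncol(m); K <- length(kernel) - 1L
  F <- matrix(0, nrow(m), T)
  for (i in seq_len(nrow(m))) {
    nz <- which(m[i, ] != 0)
    if (length(nz) > T / 8) {        # dense fallback: direct FIR filter
      acc <- numeric(T + K)
      for (u in seq_len(T)) if (m[i, u] != 0)
        acc[u:(u + K)] <- acc[u:(u + K)] + m[i, u] * kernel
      F[i, ] <- acc[seq_len(T)]
    } else {
      acc <- numeric(T + K)
      for (u in nz)
        acc[u:(u + K)] <- acc[u:(u + K)] + m[i, u] * kernel
      F[i, ] <- acc[seq_len(T)]
    }
  }
  F
}

#' One-step Hebbian weight change
#'
#' The correlational learning rule evaluated at a single time bin t:
#' \deqn{\delta V_{ij} = \Big[\sum_k kernel_k\, m_i(t - (k-1)\,dt)\Big] a_j(t)
#'       - \hat m_i(t)\, a_j(t)}
#' where \eqn{\hat m_i(t) = \sum_k V_{ik} a_k(t)} is the silently postdicted
#' motor activity.  The first term is eligibility-windowed potentiation; the
#' second is equal-time heterosynaptic depression shared by all sensory
#' afferents onto motor neuron i — its strength depends on presynaptic
#' activity but not directly on postsynaptic activation.  The returned delta
#' is unscaled; the learning loop multiplies by learning rate x dt.
#'
#' @param V \linkS4class{SynapticWeights} or a plain weight matrix.
#' @param motor,sensory rate matrices (motor x T, sensory x T), aligned.
#' @param kernel discretized eligibility kernel from
#'   \code{\link{discretizeTrace}}.
#' @param t time bin (1-based).
#' @return the weight delta matrix (motor x sensory).
#' @export
learningUpdate <- function(V, motor, sensory, kernel, t) {
  W <- if (is(V, "SynapticWeights")) V@V else as.matrix(V)
  if (nrow(W) != nrow(motor) || ncol(W) != nrow(sensory))
    stop("dimension mismatch between V, motor and sensory")
  if (!all(is.finite(motor)) || !all(is.finite(sensory)))
    stop("non-finite input rates")
  K <- length(kernel) - 1L
  idx <- t:max(1L, t - K)
  Ft <- as.vector(motor[, idx, drop = FALSE] %*% kernel[seq_along(idx)])
  at <- sensory[, t]
  tcrossprod(Ft - as.vector(W %*% at), at)
}

#' Run eligibility-weighted Hebbian learning to (near) steady state
#'
#' Iterates the learning rule over time bins and epochs.  An epoch is one
#' pass over the code's renditions; variable codes are regenerated freshly
#' every epoch (new exploration), stereotyped codes repeat.  The update is
#' online per bin, scaled by learningRate x dt.  When no learning rate is
#' given, a calibration pass sets it so that the leading eigenmode of the
#' epoch's sensory correlation matrix contracts by \code{rateScale} per
#' epoch.  The returned weights are the average of the per-epoch snapshots
#' over the final \code{tailFrac} of epochs (tail averaging suppresses the
#' stochastic-approximation noise of fresh-rendition learning without moving
#' the fixed point).
#'
#' Learning is only admissible while the gate is closed (\code{gated(V0)}
#' must be TRUE): the weights correlate silently and never drive motor
#' activity, which would otherwise bias the code being learned from (and
#' produce cyclic "stuttering" output).
#'
#' @param V0 initial \linkS4class{SynapticWeights}, gated.
#' @param code a \linkS4class{MotorCode}; its renditions define one epoch.
#' @param map a \linkS4class{MotorSensoryMap}.
#' @param trace an \linkS4class{EligibilityTrace}; must satisfy
#'   e(tau) >= traceEpsilon * e(0).
#' @param learningRate explicit step scale; NULL for calibration.
#' @param rateScale calibration target, the per-epoch contraction of the
#'   leading mode (default 0.5).
#' @param nEpochs epoch cap.
#' @param convergenceTol stop when ||epoch-mean delta V||_F / ||V||_F falls
#'   below this.
#' @param seed base seed for the per-epoch regeneration of variable codes.
#' @param tailFrac fraction of final epochs averaged into the result.
#' @param divergenceCapFactor error out when ||V||_F exceeds this multiple
#'   of the predicted causal inverse's norm (signals a too-large rate).
#' @param traceEpsilon eligibility-at-delay threshold (fraction of e(0)).
#' @return a \linkS4class{SynapticWeights} with diagnostics (update-norm
#'   trajectory, learning rate, epochs run, convergence flag).
#' @export
runLearning <- function(V0, code, map, trace, learningRate = NULL,
                        rateScale = 0.5, nEpochs = 100L,
                        convergenceTol = 1e-4, seed = 1L, tailFrac = 0.3,
                        divergenceCapFactor = 1e3, traceEpsilon = 0.05) {
  if (!gated(V0))
    stop("weights must be gated (silent) during learning")
  dt <- code@dt
  tau <- feedbackDelay(map)
  msToBins(tau, dt, "tau")
  checkTraceDelay(trace, tau, traceEpsilon)
  if (trace@kind != "custom_table" && code@t0 > 0.15 * trace@decayTime)
    warning("burst width t0 is not small relative to the eligibility decay; ",
            "closed-form predictions degrade", call. = FALSE)
  kernel <- discretizeTrace(trace, dt)
  suppb <- length(kernel) - 1L
  r <- code@renditions
  if (length(r) > 1L) {
    gapb <- min(start(r)[-1L] - end(r)[-length(r)]) - 1L
    if (gapb * dt < tau + trace@support)
      warning("rendition gap (", gapb * dt, " ms) is shorter than tau + ",
              "eligibility support; correlations straddle renditions",
              call. = FALSE)
  }

  V <- V0@V
  cap <- divergenceCapFactor *
    max(frobenius(predictedCausalInverse(map, trace, code@t0)), 1e-12)
  eta <- learningRate
  updateNorms <- numeric(0)
  snapshots <- list()
  converged <- FALSE

  for (epoch in seq_len(nEpochs)) {
    codeE <- if (epoch == 1L) code else
      regenerateCode(code, childSeed(seed, epoch))
    m <- codeE@rates
    a <- sensoryResponse(map, codeE)
    F <- eligibilityFilter(m, kernel)
    act <- which(colSums(abs(a)) > 0)

    if (is.null(eta)) {
      A1 <- tcrossprod(a[, act, drop = FALSE]) * dt
      lam <- max(eigen((A1 + t(A1)) / 2, symmetric = TRUE,
                       only.values = TRUE)$values)
      eta <- rateScale / lam
    }

    Vstart <- V
    step <- eta * dt
    for (t in act) {
      at <- a[, t]
      V <- V + step * tcrossprod(F[, t] - as.vector(V %*% at), at)
    }
    if (!all(is.finite(V)) || frobenius(V) > cap)
      stop("divergence: ||V||_F exceeded its cap; reduce the learning rate")

    # epoch-averaged update, realized as the net weight change of the epoch
    rel <- frobenius(V - Vstart) / max(frobenius(V), 1e-12)
    updateNorms <- c(updateNorms, rel)
    snapshots[[epoch]] <- V
    if (rel < convergenceTol) { converged <- TRUE; break }
  }

  nm <- length(snapshots)
  tailN <- max(1L, ceiling(tailFrac * nm))
  Vbar <- Reduce("+", snapshots[(nm - tailN + 1L):nm]) / tailN
  new("SynapticWeights", V = Vbar, learningRate = eta, gated = TRUE,
      diagnostics = list(updateNorms = updateNorms, epochs = nm,
                         converged = converged, learningRate = eta,
                         tailEpochs = tailN,
                         finalRelUpdate = updateNorms[nm]))
}

#' Closed-form causal inverse prediction
#'
#' For variable (uncorrelated) motor codes the learning steady state is the
#' inverse of the feedback map weighted by the eligibility at the loop
#' delay: \eqn{V = e(\tau)\, t_0\, Q^{-1}} (pseudo-inverse for non-square
#' full-column-rank Q, in which case the prediction is restricted to the
#' image of Q).
#'
#' @param map a \linkS4class{MotorSensoryMap}.
#' @param trace an \linkS4class{EligibilityTrace}.
#' @param t0 burst width (= motor cross-correlation width) in ms.
#' @return predicted weight matrix (motor x sensory).
#' @export
predictedCausalInverse <- function(map, trace, t0) {
  if (mapRank(map) < ncol(map@Q))
    warning("Q is rank deficient: prediction restricted to the image of Q")
  evalTrace(trace, feedbackDelay(map)) * t0 * pinv(map@Q)
}

#' Closed-form predictive inverse prediction
#'
#' For stereotyped (traveling-pulse) motor codes the steady state is
#' approximately a concatenation of the inverse of Q with a shifter matrix
#' that advances motor activity by the loop delay:
#' \eqn{V \simeq e(0)\, t_0\, H^{\tau} Q^{-1}}.  A sensory pattern caused by
#' motor neuron i then maps onto the motor neurons active tau later — those
#' most recently active when the feedback arrives.  The approximation keeps
#' only the dominant term of the exact steady state (see
#' \code{\link{steadyStateWeights}} and the methods vignette) and degrades
#' when the eligibility decays slowly relative to the inter-burst lag.
#'
#' @inheritParams predictedCausalInverse
#' @param shifter a \linkS4class{ShifterMatrix} consistent with the code and
#'   delay (see \code{\link{shifterFromCode}}).
#' @return predicted weight matrix (motor x sensory).
#' @export
predictedPredictiveInverse <- function(map, trace, t0, shifter) {
  if (mapRank(map) < ncol(map@Q))
    warning("Q is rank deficient: prediction restricted to the image of Q")
  evalTrace(trace, 0) * t0 * shifter@H %*% pinv(map@Q)
}

#' Shifter matrix of a stereotyped code
#'
#' H[i, j] = 1 iff neuron i bursts exactly tau after neuron j (onset match
#' within half a burst width), so H maps the motor population state at time
#' t onto the state at t + tau.  Cyclic codes wrap the sequence around.
#'
#' @param code a stereotyped \linkS4class{MotorCode}.
#' @param tau the advance in ms.
#' @return a \linkS4class{ShifterMatrix}.
#' @export
shifterFromCode <- function(code, tau) {
  if (code@codeKind != "stereotyped")
    stop("shifter matrices are defined for stereotyped codes")
  on <- code@params$onsetsMs          # neurons x cycles
  n <- nrow(on)
  H <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (any(abs(outer(on[i, ], on[j, ] + tau, "-")) <= code@t0 / 2))
      H[i, j] <- 1
  if (all(H == 0))
    stop("no match: tau = ", tau,
         " ms is incommensurate with the code's inter-burst lag")
  new("ShifterMatrix", H = H, tau = tau)
}

#' Empirical steady state of the learning rule
#'
#' The exact fixed point of the epoch-averaged rule on a given code,
#' computed in closed form rather than by online iteration:
#' \eqn{V^* = \langle F a^T \rangle \langle a a^T \rangle^{+}} with F the
#' eligibility-filtered motor trace.  For stereotyped codes this exposes the
#' full "eligibility comb" — weight mass on every inter-burst diagonal,
#' weighted by the trace — of which the single-shifter closed form keeps
#' only the dominant tooth.  Used as an independent oracle for the online
#' learner.
#'
#' @param code a \linkS4class{MotorCode}.
#' @param map a \linkS4class{MotorSensoryMap}.
#' @param trace an \linkS4class{EligibilityTrace}.
#' @return weight matrix (motor x sensory).
#' @export
steadyStateWeights <- function(code, map, trace) {
  dt <- code@dt
  kernel <- discretizeTrace(trace, dt)
  m <- code@rates
  a <- sensoryResponse(map, code)
  F <- eligibilityFilter(m, kernel)
  act <- which(colSums(abs(a)) > 0)
  aA <- a[, act, drop = FALSE]
  P <- tcrossprod(F[, act, drop = FALSE], aA) * dt
  A <- tcrossprod(aA) * dt
  P %*% pinv(A)
}

## ---- accessors & show ----

#' @rdname accessors
#' @export
setMethod("weightMatrix", "SynapticWeights", function(x) x@V)

#' @rdname accessors
#' @export
setMethod("gated", "SynapticWeights", function(x) x@gated)

#' @rdname accessors
#' @export
setReplaceMethod("gated", "SynapticWeights", function(x, value) {
  x@gated <- as.logical(value)
  x
})

setMethod("show", "SynapticWeights", function(object) {
  d <- object@diagnostics
  cat(sprintf("SynapticWeights: %d motor x %d sensory, gate %s\n",
              nrow(object@V), ncol(object@V),
              if (object@gated) "closed (learning)" else "open (playback)"))
  if (length(d))
    cat(sprintf("  %d epochs, eta = %.3g, final rel. update %.3g (%s)\n",
                d$epochs, d$learningRate, d$finalRelUpdate,
                if (isTRUE(d$converged)) "converged" else "epoch cap"))
})

setMethod("show", "ShifterMatrix", function(object) {
  cat(sprintf("ShifterMatrix: advance tau = %g ms\n", object@tau))
  print(object@H)
})

#' @export
#' @rdname ShifterMatrix-class
#' @param x a \code{ShifterMatrix}.
#' @param ... ignored.
setMethod("as.matrix", "ShifterMatrix", function(x, ...) x@H)
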