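#' Construct a binary mirroring channel
#'
#' Two-state probabilistic model of mirroring strength: a binary motor state
#' M (the motor area is either active or not, prior \code{pM1}) and a binary
#' sensory detection S of a particular feature, coupled by the tuning
#' probabilities p(S=1|M=1) and p(S=1|M=0).  Intrinsic noise is modelled as
#' independent symmetric bit flips applied to each variable.
#'
#' @param pS1gM1,pS1gM0 detection probabilities given the motor state.
#' @param pM1 prior probability of M = 1.
#' @param motorNoise,sensorNoise symmetric flip probabilities in [0, 1/2].
#' @return a \linkS4class{BinaryMirrorChannel}.
#' @export
binaryMirrorChannel <- function(pS1gM1, pS1gM0, pM1 = 0.5, motorNoise = 0,
                                sensorNoise = 0) {
  new("BinaryMirrorChannel", pM1 = pM1, pS1gM1 = pS1gM1, pS1gM0 = pS1gM0,
      motorNoise = motorNoise, sensorNoise = sensorNoise)
}

#' Joint distribution of the observed (M, S) pair
#'
#' Exact 2 x 2 table p(M, S) with the flip noise applied to each variable
#' independently.
#'
#' @param channel a \linkS4class{BinaryMirrorChannel}.
#' @return 2 x 2 matrix, rows M in {0, 1}, columns S in {0, 1}.
#' @export
#' @examples
#' jointDistribution(binaryMirrorChannel(1, 0))  # diag(1/2, 1/2)
jointDistribution <- function(channel) {
  flip <- function(nu) matrix(c(1 - nu, nu, nu, 1 - nu), 2, 2)  # symmetric
  pM <- c(1 - channel@pM1, channel@pM1)
  pSgM <- rbind(c(1 - channel@pS1gM0, channel@pS1gM0),
                c(1 - channel@pS1gM1, channel@pS1gM1))  # rows M, cols S
  joint <- pM * pSgM                                   # true (M, S)
  out <- flip(channel@motorNoise) %*% joint %*% flip(channel@sensorNoise)
  dimnames(out) <- list(M = c("0", "1"), S = c("0", "1"))
  out
}

# Pearson correlation of two binary variables from their 2x2 joint.
.binCor <- function(joint) {
  pm <- sum(joint[2, ]); ps <- sum(joint[, 2])
  vm <- pm * (1 - pm); vs <- ps * (1 - ps)
  if (vm <= 0 || vs <= 0) {
    warning("degenerate marginal: correlation undefined")
    return(NA_real_)
  }
  (joint[2, 2] - pm * ps) / sqrt(vm * vs)
}

#' Exact mirroring correlation coefficient
#'
#' Pearson correlation between the observed motor state and the observed
#' sensory detection, computed exactly by enumeration of the four outcomes.
#' For a perfectly tuned, unbiased detector (no sensor/motor noise and
#' p(S=1|M=0) = 1 - p(S=1|M=1), so the feature is detected half the time
#' overall) the coefficient equals the tuning difference
#' p(S=1|M=1) - p(S=1|M=0): mirrored responses are as strong as the motor
#' neuron's contribution to generating the detected feature.
#'
#' @param channel a \linkS4class{BinaryMirrorChannel}.
#' @return correlation in [-1, 1]; NA with a warning when a marginal is
#'   degenerate.
#' @export
correlationCoefficient <- function(channel) .binCor(jointDistribution(channel))

#' Monte-Carlo estimate of the mirroring correlation
#'
#' Sampling cross-check for \code{\link{correlationCoefficient}}: draws
#' (M, S) pairs from the channel (including flip noise) and returns their
#' sample Pearson correlation.
#'
#' @param channel a \linkS4class{BinaryMirrorChannel}.
#' @param nSamples number of samples (>= 1).
#' @param seed integer seed.
#' @return sample correlation.
#' @export
monteCarloCorrelation <- function(channel, nSamples, seed = 1L) {
  stopifnot(nSamples >= 1)
  withSeed(seed, {
    M <- as.numeric(runif(nSamples) < channel@pM1)
    pS <- ifelse(M == 1, channel@pS1gM1, channel@pS1gM0)
    S <- as.numeric(runif(nSamples) < pS)
    if (channel@motorNoise > 0)
      M <- abs(M - (runif(nSamples) < channel@motorNoise))
    if (channel@sensorNoise > 0)
      S <- abs(S - (runif(nSamples) < channel@sensorNoise))
    if (sd(M) == 0 || sd(S) == 0) return(NA_real_)
    cor(M, S)
  })
}

#' Mirroring strength through a learned binary readout under intrinsic noise
#'
#' In the noisy regime the mirrored response is not the sensory detection
#' itself but a motor reactivation driven through a weight learned from the
#' noisy motor-sensory contingency.  This models that two-stage pathway
#' exactly: (i) Hebbian learning sets the readout weight to the observed
#' covariance, w = Cov(M, S) (flip noise included on both variables);
#' (ii) during playback a fresh episode of the channel drives a stochastic
#' binary response R with p(R=1 | S) = 1/2 + gain * w * (S - E[S]) — a
#' noisy neuron whose intrinsic variability dominates its drive.  The
#' returned coefficient corr(M, R), computed by exact enumeration, is
#' positive and proportional to the squared tuning difference
#' (p(S=1|M=1) - p(S=1|M=0))^2: the tuning enters once through the learned
#' weight and once through the replayed correlation, while the response
#' variance is fixed by the intrinsic noise.  Equal intrinsic noise nu on
#' both variables attenuates it by (1-2 nu)^4.
#'
#' @param channel a \linkS4class{BinaryMirrorChannel}.
#' @param gain readout gain (kept small enough that response probabilities
#'   stay in [0, 1]; validated).
#' @return corr(M, R) in [-1, 1].
#' @export
mirroringCoefficient <- function(channel, gain = 1) {
  joint <- jointDistribution(channel)
  ES <- sum(joint[, 2])
  pm <- sum(joint[2, ])
  w <- joint[2, 2] - pm * ES            # learned weight = Cov(M, S)
  pR <- function(s) 0.5 + gain * w * (s - ES)
  if (pR(0) < 0 || pR(0) > 1 || pR(1) < 0 || pR(1) > 1)
    stop("gain too large: response probability leaves [0, 1]")
  ## enumerate (M, S, R)
  pMR <- matrix(0, 2, 2, dimnames = list(M = c("0", "1"), R = c("0", "1")))
  for (mi in 1:2) for (si in 1:2) {
    p1 <- pR(si - 1)
    pMR[mi, 2] <- pMR[mi, 2] + joint[mi, si] * p1
    pMR[mi, 1] <- pMR[mi, 1] + joint[mi, si] * (1 - p1)
  }
  .binCor(pMR)
}

setMethod("show", "BinaryMirrorChannel", function(object) {
  cat(sprintf(
    "BinaryMirrorChannel: p(M=1) = %g, p(S=1|M=1) = %g, p(S=1|M=0) = %g\n",
    object@pM1, object@pS1gM1, object@pS1gM0))
  if (object@motorNoise > 0 || object@sensorNoise > 0)
    cat(sprintf("  flip noise: motor %g, sensor %g\n", object@motorNoise,
                object@sensorNoise))
})
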