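#' Construct a motor-sensory map
#'
#' @param Q numeric matrix (sensory x motor).
#' @param tauM,tauA motor-to-behaviour and behaviour-to-sensory delays (ms);
#'   only their sum enters the sensory response.
#' @return a \linkS4class{MotorSensoryMap}.
#' @export
motorSensoryMap <- function(Q, tauM = 0, tauA = 0) {
  Q <- as.matrix(Q)
  new("MotorSensoryMap", Q = Q, tauM = tauM, tauA = tauA,
      rank = qr(Q)$rank)
}

#' Delayed sensory response to a motor code
#'
#' Applies the linear feedback model a(t) = Q m(t - tau) on the motor code's
#' time base, with zero history for t < tau.
#'
#' @param map a \linkS4class{MotorSensoryMap}.
#' @param motor a \linkS4class{MotorCode} or a rate matrix (motor x time).
#' @param dt bin width in ms, needed when \code{motor} is a plain matrix.
#' @return rate matrix, sensory x time, aligned with the motor time base.
#' @export
#' @examples
#' m <- generateStereotypedCode(2, 1, interBurstLag = 20)
#' a <- sensoryResponse(motorSensoryMap(diag(2), 10, 5), m)
sensoryResponse <- function(map, motor, dt = NULL) {
  m <- if (is(motor, "MotorCode")) motor@rates else as.matrix(motor)
  if (is(motor, "MotorCode")) dt <- motor@dt
  if (is.null(dt)) stop("dt must be given for plain matrices")
  if (ncol(map@Q) != nrow(m))
    stop("dimension mismatch: Q has ", ncol(map@Q), " motor columns, code has ",
         nrow(m), " neurons")
  if (any(!is.finite(m))) stop("non-finite motor rates")
  taub <- msToBins(feedbackDelay(map), dt, "tau")
  T <- ncol(m)
  a <- matrix(0, nrow(map@Q), T)
  if (taub < T)
    a[, (taub + 1L):T] <- map@Q %*% m[, seq_len(T - taub), drop = FALSE]
  a
}

#' Random well-conditioned motor-sensory map
#'
#' Draws Q with i.i.d. standard normal entries and resamples until the
#' condition number (ratio of extreme non-zero singular values) is at most
#' \code{conditionCap}.  Full column rank requires \code{nSensory >=
#' nMotor}.  The default cap keeps the feedback loop well conditioned; the
#' time for the slowest weight mode to converge grows with the square of the
#' condition number.
#'
#' @param nMotor,nSensory dimensions of the map.
#' @param tauM,tauA delays in ms.
#' @param conditionCap upper bound on cond(Q).
#' @param seed integer seed.
#' @param maxIter resampling cap; exceeded -> error.
#' @return a \linkS4class{MotorSensoryMap} with full column rank.
#' @export
randomInvertibleMap <- function(nMotor, nSensory = nMotor, tauM = 25,
                                tauA = 15, conditionCap = 5, seed = 1L,
                                maxIter = 1000L) {
  stopifnot(nSensory >= nMotor)
  Q <- withSeed(seed, {
    for (it in seq_len(maxIter)) {
      Qc <- matrix(rnorm(nSensory * nMotor), nSensory, nMotor)
      d <- svd(Qc, nu = 0, nv = 0)$d
      if (d[nMotor] > 0 && d[1] / d[nMotor] <= conditionCap) break
      Qc <- NULL
    }
    Qc
  })
  if (is.null(Q))
    stop("giving up: no map with cond(Q) <= ", conditionCap, " in ",
         maxIter, " draws")
  motorSensoryMap(Q, tauM = tauM, tauA = tauA)
}

## ---- accessors & show ----

#' @rdname accessors
#' @export
setMethod("feedbackMatrix", "MotorSensoryMap", function(x) x@Q)

#' @rdname accessors
#' @export
setMethod("feedbackDelay", "MotorSensoryMap", function(x) x@tauM + x@tauA)

#' @rdname accessors
#' @export
setMethod("mapRank", "MotorSensoryMap", function(x) x@rank)

setMethod("show", "MotorSensoryMap", function(object) {
  cat(sprintf(
    "MotorSensoryMap: %d sensory x %d motor, rank %d, tau = %g ms (%g + %g)\n",
    nrow(object@Q), ncol(object@Q), object@rank,
    object@tauM + object@tauA, object@tauM, object@tauA))
})
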