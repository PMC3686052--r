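#' Construct an eligibility trace
#'
#' The eligibility trace e(s) is the postsynaptic gain with which a sensory
#' input arriving s ms after motor firing can potentiate the synapse.  It
#' must bridge the sensorimotor loop delay tau, i.e. e(tau) must remain well
#' above zero.  Built-in kinds:
#' \describe{
#'   \item{exponential}{e(s) = e0 exp(-s / decayTime)}
#'   \item{linear_decay}{e(s) = e0 max(0, 1 - s / decayTime)}
#'   \item{custom_table}{values sampled on a uniform grid; must be monotone
#'     non-increasing unless \code{nonMonotone = TRUE} (traces peaking at the
#'     loop delay are constructible but flagged).}
#' }
#'
#' The default decay time used by the experiment layer is twice the loop
#' delay, so e(tau)/e(0) = exp(-1/2) ~ 0.61: comfortably "eligible at the
#' loop delay" while leaving a measurable peak-ratio prediction.
#'
#' @param kind trace kind, see above.
#' @param e0 gain at s = 0.
#' @param decayTime decay constant (exponential) or time-to-zero (linear), ms.
#' @param support truncation horizon in ms; defaults to 5 decay times for the
#'   exponential (<1% of the mass discarded) and decayTime for linear decay.
#' @param table sampled values for \code{custom_table}.
#' @param tableDt sampling step of \code{table} in ms.
#' @param nonMonotone allow non-monotone custom tables.
#' @return an \linkS4class{EligibilityTrace}.
#' @export
#' @examples
#' tr <- eligibilityTrace("exponential", decayTime = 80)
#' evalTrace(tr, 80) / evalTrace(tr, 0)  # exp(-1)
eligibilityTrace <- function(kind = c("exponential", "linear_decay",
                                      "custom_table"),
                             e0 = 1, decayTime = 80, support = NULL,
                             table = numeric(), tableDt = 1,
                             nonMonotone = FALSE) {
  kind <- match.arg(kind)
  if (is.null(support))
    support <- switch(kind,
      exponential = 5 * decayTime,
      linear_decay = decayTime,
      custom_table = (length(table) - 1) * tableDt)
  new("EligibilityTrace", kind = kind, e0 = e0, decayTime = decayTime,
      support = support, table = as.numeric(table), tableDt = tableDt,
      nonMonotone = nonMonotone)
}

#' Evaluate an eligibility trace
#'
#' @param trace an \linkS4class{EligibilityTrace}.
#' @param s lag(s) in ms, all >= 0.
#' @return e(s), zero beyond the support.
#' @export
evalTrace <- function(trace, s) {
  if (any(s < 0)) stop("negative lag: eligibility is defined for s >= 0")
  v <- switch(trace@kind,
    exponential = trace@e0 * exp(-s / trace@decayTime),
    linear_decay = trace@e0 * pmax(0, 1 - s / trace@decayTime),
    custom_table = {
      idx <- s / trace@tableDt
      lo <- pmin(floor(idx), length(trace@table) - 1)
      frac <- idx - lo
      lo1 <- pmin(lo + 1, length(trace@table))
      hi <- pmin(lo + 2, length(trace@table))
      trace@table[lo1] * (1 - frac) + trace@table[hi] * frac
    })
  v[s > trace@support] <- 0
  v
}

#' Discretize an eligibility trace into an integration kernel
#'
#' Returns \code{kernel[k] = e((k-1) dt) dt} for k = 1..support/dt + 1, so
#' that the learning rule's integral of e(s) m(t - s) ds is approximated by
#' \code{sum_k kernel[k] m(t - (k-1) dt)} (rectangle rule on the dt grid).
#'
#' @param trace an \linkS4class{EligibilityTrace}.
#' @param dt bin width in ms.
#' @return numeric kernel vector.
#' @export
discretizeTrace <- function(trace, dt) {
  stopifnot(dt > 0)
  K <- floor(trace@support / dt + 1e-9)
  evalTrace(trace, (0:K) * dt) * dt
}

#' Total mass of a trace, \eqn{\int_0^{support} e(s) ds}
#'
#' The learning rule equals exact gradient descent on the postdiction error
#' only when this mass is 1; see the methods vignette.
#'
#' @param trace an \linkS4class{EligibilityTrace}.
#' @param dt integration step in ms.
#' @return the trace mass.
#' @export
traceMass <- function(trace, dt = 0.1) sum(discretizeTrace(trace, dt))

# Check that the trace bridges the loop delay: e(tau) >= epsilon * e(0).
checkTraceDelay <- function(trace, tau, epsilon = 0.05) {
  e0 <- evalTrace(trace, 0)
  if (e0 <= 0 || evalTrace(trace, tau) < epsilon * e0)
    stop(sprintf(
      "eligibility at the loop delay is too small: e(%g) < %g * e(0); %s",
      tau, epsilon,
      "the trace cannot bridge the sensory feedback delay"), call. = FALSE)
  invisible(TRUE)
}

setMethod("show", "EligibilityTrace", function(object) {
  cat(sprintf("EligibilityTrace (%s): e0 = %g, decay = %g ms, support = %g ms%s\n",
              object@kind, object@e0, object@decayTime, object@support,
              if (object@nonMonotone) " [non-monotone]" else ""))
})
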