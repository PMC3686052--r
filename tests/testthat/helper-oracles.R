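# Independent oracles and small fixtures used across the tests.

# O(T * L) nested-loop cross-covariance with full-window means, the brute
# oracle for crossCorrelation().
oracleXcov <- function(x, y, maxLagBins) {
  T <- length(x)
  xm <- x - mean(x); ym <- y - mean(y)
  sapply(-maxLagBins:maxLagBins, function(s) {
    acc <- 0; n <- 0
    for (t in seq_len(T)) {
      u <- t + s
      if (u >= 1 && u <= T) { acc <- acc + xm[t] * ym[u]; n <- n + 1 }
    }
    acc / n
  })
}

# Central finite differences of the eligibility-weighted postdiction error
#   E_t(V) = 1/2 sum_i sum_k kernel[k] (m_i(t-k+1) - sum_j V_ij a_j(t))^2
# evaluated at bin t (t must exceed the kernel length).
oracleGradient <- function(V, m, a, kernel, t, h = 1e-5) {
  Efun <- function(W) {
    K <- length(kernel)
    mhat <- as.vector(W %*% a[, t])
    acc <- 0
    for (k in seq_len(K)) {
      d <- m[, t - k + 1] - mhat
      acc <- acc + kernel[k] * sum(d^2)
    }
    acc / 2
  }
  G <- matrix(0, nrow(V), ncol(V))
  for (i in seq_len(nrow(V))) for (j in seq_len(ncol(V))) {
    hp <- h * max(1, abs(V[i, j]))
    Vp <- V; Vp[i, j] <- V[i, j] + hp
    Vm <- V; Vm[i, j] <- V[i, j] - hp
    G[i, j] <- (Efun(Vp) - Efun(Vm)) / (2 * hp)
  }
  G
}

# A fixed, well-conditioned 4x4 test loop shared by several tests.
testLoop <- function(seed = 3, n = 4, decay = 80, tauM = 25, tauA = 15) {
  map <- randomInvertibleMap(n, n, tauM = tauM, tauA = tauA,
                             conditionCap = 5, seed = seed)
  trace <- eligibilityTrace("exponential", decayTime = decay)
  list(map = map, trace = trace, tau = tauM + tauA,
       gap = trace@support + tauM + tauA)
}

relF <- function(A, B) sqrt(sum((A - B)^2)) / sqrt(sum(B^2))
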