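test_that("single-bin updates follow the rule's two terms", {
  trace <- eligibilityTrace("exponential", decayTime = 80)
  kern <- discretizeTrace(trace, 1)
  # no presynaptic activity: both terms vanish
  m <- matrix(runif(3 * 100), 3)
  a0 <- matrix(0, 3, 100)
  V <- matrix(rnorm(9), 3)
  expect_equal(learningUpdate(V, m, a0, kern, 70), matrix(0, 3, 3))

  # pure potentiation: V = 0, one motor pulse at t - tau, one sensory pulse
  # at t -> only delta V_ij = kernel[tau/dt + 1] * m * a survives
  tau <- 40
  m1 <- matrix(0, 3, 200); m1[2, 150 - tau] <- 1.5
  a1 <- matrix(0, 4, 200); a1[3, 150] <- 2
  d <- learningUpdate(matrix(0, 3, 4), m1, a1, kern, 150)
  expect_equal(d[2, 3], kern[tau + 1] * 1.5 * 2)
  d[2, 3] <- 0
  expect_equal(d, matrix(0, 3, 4))

  # heterosynaptic depression does not depend on postsynaptic (filtered
  # motor) activity: with silent motor past, delta V = -(V a) a^T
  mq <- matrix(0, 3, 100)
  aq <- matrix(runif(4 * 100), 4)
  Vq <- matrix(rnorm(12), 3, 4)
  expect_equal(learningUpdate(Vq, mq, aq, kern, 80),
               -tcrossprod(as.vector(Vq %*% aq[, 80]), aq[, 80]))
  expect_error(learningUpdate(matrix(0, 2, 2), m1, a1, kern, 10),
               "dimension mismatch")
})

test_that("the update is the negative gradient of the postdiction error", {
  # exact for unit-mass kernels; the depression term otherwise carries the
  # trace mass (checked below)
  set.seed(21)
  worst <- 0
  for (rep in 1:25) {
    nm <- sample(2:4, 1); na <- sample(2:4, 1); T <- 50
    lam <- runif(1, 3, 8)
    kern <- exp(-(0:round(3 * lam)) / lam)
    kern <- kern / sum(kern)             # unit mass
    m <- matrix(runif(nm * T), nm)
    a <- matrix(runif(na * T), na)
    V <- matrix(rnorm(nm * na, sd = 0.5), nm, na)
    t <- sample((length(kern) + 1):T, 1)
    upd <- learningUpdate(V, m, a, kern, t)
    g <- oracleGradient(V, m, a, kern, t)
    worst <- max(worst, sqrt(sum((upd + g)^2)) / sqrt(sum(upd^2)))
  }
  expect_lt(worst, 1e-6)

  # non-unit mass: -grad = F a^T - mass * postdiction * a^T
  kern2 <- exp(-(0:20) / 6) * 0.8
  mass <- sum(kern2)
  m <- matrix(runif(3 * 60), 3); a <- matrix(runif(3 * 60), 3)
  V <- matrix(rnorm(9), 3)
  t <- 40
  upd <- learningUpdate(V, m, a, kern2, t)
  g <- oracleGradient(V, m, a, kern2, t)
  extra <- (mass - 1) * tcrossprod(as.vector(V %*% a[, t]), a[, t])
  expect_equal(-g, upd - extra, tolerance = 1e-6)
})

test_that("scalar loops converge to the scalar inverse", {
  # Q = c I, tau = 0: V -> diagonal proportional to 1/c
  cscale <- 2.5
  map <- motorSensoryMap(cscale * diag(2), tauM = 0, tauA = 0)
  trace <- eligibilityTrace("exponential", decayTime = 80)
  code <- generateVariableCode(2, 20, renditionLen = 4000, gap = 440,
                               seed = 31)
  W <- runLearning(synapticWeights(nMotor = 2, nSensory = 2), code, map,
                   trace, nEpochs = 40, rateScale = 1, seed = 32)
  # diagonal, with both entries proportional to 1/c.  (At zero delay the
  # correlation tooth straddles s = 0, so the absolute constant is about
  # half of e(0) t0; the inverse structure is what matters here.)
  M <- weightMatrix(W) %*% feedbackMatrix(map)   # = V * c
  expect_lt(abs(M[1, 2]) + abs(M[2, 1]), 0.15 * mean(diag(M)))
  expect_equal(M[1, 1], M[2, 2], tolerance = 0.1)
  expect_equal(weightMatrix(W)[1, 1] / weightMatrix(W)[2, 2],
               1, tolerance = 0.1)
})

test_that("stereotyped learning lands on the exact comb steady state", {
  lp <- testLoop(seed = 3)
  code <- generateStereotypedCode(4, 1, interBurstLag = 20, gap = lp$gap)
  W <- runLearning(synapticWeights(nMotor = 4, nSensory = 4), code,
                   lp$map, lp$trace, nEpochs = 500, convergenceTol = 1e-7,
                   tailFrac = 0.05, seed = 4)
  Vexact <- steadyStateWeights(code, lp$map, lp$trace)
  expect_lt(relF(weightMatrix(W), Vexact), 0.03)
  # the comb: in V Q, the tooth at inter-burst diagonal d carries
  # eligibility e(tau - d * lag); the strongest full tooth is d = 1 here
  M <- weightMatrix(W) %*% feedbackMatrix(lp$map)
  e <- function(s) evalTrace(lp$trace, s)
  expect_equal(M[3, 2] / M[3, 3], e(20) / e(40) * 10 / 10, tolerance = 0.05)
  expect_equal(M[2, 1], 10 * e(20), tolerance = 0.5)
})

test_that("closed-form predictions obey their defining contracts", {
  lp <- testLoop(seed = 9)
  t0 <- 10
  # causal: V Q = e(tau) t0 I on the motor space
  Vc <- predictedCausalInverse(lp$map, lp$trace, t0)
  expect_equal(Vc %*% feedbackMatrix(lp$map),
               evalTrace(lp$trace, lp$tau) * t0 * diag(4),
               tolerance = 1e-10)
  # hand 2x2 example
  Q <- rbind(c(2, 0), c(1, 1))
  mh <- motorSensoryMap(Q, tauM = 40)
  trh <- eligibilityTrace("custom_table", table = c(0.5, 0.5), tableDt = 40)
  expect_equal(predictedCausalInverse(mh, trh, 10),
               0.5 * 10 * rbind(c(0.5, 0), c(-0.5, 1)), tolerance = 1e-12)

  # predictive with H = I (tau = 0) reduces to the causal form at e(0)
  sh0 <- new("ShifterMatrix", H = diag(4), tau = 0)
  map0 <- motorSensoryMap(feedbackMatrix(lp$map), tauM = 0, tauA = 0)
  expect_equal(predictedPredictiveInverse(map0, lp$trace, t0, sh0),
               predictedCausalInverse(map0, lp$trace, t0))
  # traveling pulse with lag = tau: V Q = e(0) t0 (index shift by 1)
  code <- generateStereotypedCode(3, 1, interBurstLag = 40, gap = 500)
  map3 <- randomInvertibleMap(3, 3, tauM = 25, tauA = 15, seed = 12)
  sh <- shifterFromCode(code, 40)
  P <- matrix(0, 3, 3); P[cbind(2:3, 1:2)] <- 1
  expect_equal(as.matrix(sh), P)
  Vp <- predictedPredictiveInverse(map3, lp$trace, t0, sh)
  expect_equal(Vp %*% feedbackMatrix(map3),
               evalTrace(lp$trace, 0) * t0 * P, tolerance = 1e-10)
})

test_that("shifters follow onset differences, including cyclic wraps", {
  code <- generateStereotypedCode(4, 1, interBurstLag = 20, gap = 500)
  expect_equal(as.matrix(shifterFromCode(code, 0)), diag(4))
  H1 <- as.matrix(shifterFromCode(code, 20))
  expect_equal(H1, rbind(0, cbind(diag(3), 0)))
  H2 <- as.matrix(shifterFromCode(code, 40))   # onset enumeration: shift 2
  expect_equal(which(H2 == 1, arr.ind = TRUE)[, "row"] -
               which(H2 == 1, arr.ind = TRUE)[, "col"], c(2, 2),
               ignore_attr = TRUE)
  expect_error(shifterFromCode(code, 30), "incommensurate")
  # cyclic code: the last neuron wraps onto the first
  cyc <- generateStereotypedCode(4, 1, interBurstLag = 40, cycles = 3,
                                 gap = 500)
  Hc <- as.matrix(shifterFromCode(cyc, 40))
  expect_equal(Hc[1, 4], 1)
  expect_equal(diag(Hc %*% t(Hc)), rep(1, 4))  # a permutation
})

test_that("learning requires a closed gate and bounded weights", {
  lp <- testLoop()
  code <- generateStereotypedCode(4, 1, interBurstLag = 20, gap = lp$gap)
  V0open <- synapticWeights(nMotor = 4, nSensory = 4, gated = FALSE)
  expect_error(runLearning(V0open, code, lp$map, lp$trace), "gated")
  expect_error(
    runLearning(synapticWeights(nMotor = 4, nSensory = 4), code, lp$map,
                lp$trace, learningRate = 1e4, nEpochs = 5, seed = 2),
    "divergence")
})

test_that("weights stay bounded well past the convergence horizon", {
  lp <- testLoop(seed = 17)
  code <- generateVariableCode(3, 10, renditionLen = 2000, gap = lp$gap,
                               seed = 18)
  map3 <- randomInvertibleMap(3, 3, tauM = 25, tauA = 15, seed = 19)
  W <- runLearning(synapticWeights(nMotor = 3, nSensory = 3), code, map3,
                   lp$trace, nEpochs = 120, rateScale = 1, seed = 20,
                   tailFrac = 0.05)
  pred <- predictedCausalInverse(map3, lp$trace, 10)
  # heterosynaptic depression keeps ||V|| near the fixed point, an order
  # of magnitude below the divergence regime
  expect_lt(sqrt(sum(weightMatrix(W)^2)), 3 * sqrt(sum(pred^2)))
  expect_true(all(is.finite(weightMatrix(W))))
})

test_that("recovery error shrinks with the number of renditions", {
  lp <- testLoop(seed = 23)
  pred <- predictedCausalInverse(lp$map, lp$trace, 10)
  errAt <- function(nEpochs) {
    code <- generateVariableCode(4, 15, renditionLen = 4000, gap = lp$gap,
                                 seed = 24)
    W <- runLearning(synapticWeights(nMotor = 4, nSensory = 4), code,
                     lp$map, lp$trace, nEpochs = nEpochs, rateScale = 1,
                     seed = 25)
    relF(weightMatrix(W), pred)
  }
  errs <- c(errAt(5), errAt(25), errAt(90))
  expect_lt(errs[2], errs[1])
  expect_lt(errs[3], errs[1] / 2)
})

test_that("learned inverses only respond inside the image of Q", {
  # N_a > N_m: sensory patterns orthogonal to image(Q) were never
  # experienced and map to (near) nothing
  map <- randomInvertibleMap(3, 6, tauM = 25, tauA = 15, seed = 26)
  trace <- eligibilityTrace("exponential", decayTime = 80)
  code <- generateVariableCode(3, 15, renditionLen = 3000,
                               gap = trace@support + 40, seed = 27)
  W <- runLearning(synapticWeights(nMotor = 3, nSensory = 6), code, map,
                   trace, nEpochs = 40, rateScale = 1, seed = 28)
  Q <- feedbackMatrix(map)
  qr <- qr(Q)
  img <- qr.Q(qr)[, 1:3]
  orth <- qr.Q(qr, complete = TRUE)[, 4:6]
  nImg <- apply(img, 2, function(v) sqrt(sum((weightMatrix(W) %*% v)^2)))
  nOrth <- apply(orth, 2, function(v) sqrt(sum((weightMatrix(W) %*% v)^2)))
  expect_lt(max(nOrth) / min(nImg), 0.1)
})

test_that("the predicted causal inverse is a fixed point of learning", {
  # the rendition-averaged update nearly vanishes at V = e(tau) t0 Q^-1,
  # far below its magnitude at distant weights; the small residual is the
  # finite-burst-density bias discussed in the methods vignette
  lp <- testLoop(seed = 33)
  pred <- predictedCausalInverse(lp$map, lp$trace, 10)
  kern <- discretizeTrace(lp$trace, 1)
  meanUpd <- function(V, nrend, seed) {
    code <- generateVariableCode(4, nrend, renditionLen = 8000,
                                 gap = lp$gap, seed = seed)
    m <- rates(code)
    a <- sensoryResponse(lp$map, code)
    F <- mirrorloop:::eligibilityFilter(m, kern)
    act <- which(colSums(abs(a)) > 0)
    S <- matrix(0, 4, 4)
    for (t in act)
      S <- S + tcrossprod(F[, t] - as.vector(V %*% a[, t]), a[, t])
    sqrt(sum((S / nrend)^2))
  }
  uPred <- meanUpd(pred, 120, 41)
  uZero <- meanUpd(matrix(0, 4, 4), 120, 41)
  uHalf <- meanUpd(pred / 2, 120, 41)
  expect_lt(uPred, 0.2 * uZero)
  expect_lt(uPred, 0.3 * uHalf)
})
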