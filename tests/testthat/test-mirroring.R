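test_that("playback responses require an open gate", {
  V <- synapticWeights(diag(2), gated = TRUE)
  a <- matrix(runif(2 * 50), 2)
  expect_error(playbackResponse(V, a), "gate is closed")
  gated(V) <- FALSE
  expect_equal(playbackResponse(V, a), a)
  # hand-built 2x2
  Vh <- synapticWeights(rbind(c(1, 2), c(0, -1)), gated = FALSE)
  ah <- matrix(0, 2, 10); ah[1, 3] <- 1; ah[2, 7] <- 2
  mh <- playbackResponse(Vh, ah)
  expect_equal(mh[, 3], c(1, 0))
  expect_equal(mh[, 7], c(4, -2))
  expect_error(playbackResponse(Vh, matrix(0, 3, 5)), "dimension")
})

test_that("a delayed copy yields an offset equal to the delay", {
  code <- generateVariableCode(3, 10, renditionLen = 500, t0 = 10,
                               seed = 51)
  m <- rates(code)
  tau <- 40
  pb <- cbind(matrix(0, 3, tau), m[, 1:(ncol(m) - tau)])
  res <- mirroringOffset(code, pb, maxLag = 80)
  expect_equal(offsets(res), rep(40, 3))
  expect_equal(peakValues(res), rep(1, 3), tolerance = 0.05)
})

test_that("offset dichotomy: causal runs lag by tau, predictive by less", {
  lp <- testLoop(seed = 61)
  # causal: variable exploration
  codeV <- generateVariableCode(4, 15, renditionLen = 4000, gap = lp$gap,
                                seed = 62)
  rv <- runMirroringExperiment(codeV, lp$map, lp$trace, nEpochs = 30,
                               seed = 63)
  expect_true(abs(median(offsets(rv$result)) - lp$tau) <= 5)

  # predictive, default (shallow) trace: offsets collapse from tau down to
  # the inter-burst lag — the zero-lag tooth of the eligibility comb is
  # halved, so e(lag) wins over e(0)/2 for slowly decaying traces
  codeS <- generateStereotypedCode(4, 1, interBurstLag = 20, gap = lp$gap)
  rs <- runMirroringExperiment(codeS, lp$map, lp$trace, nEpochs = 400,
                               convergenceTol = 1e-7, tailFrac = 0.05,
                               seed = 64)
  expect_true(median(offsets(rs$result)) >= 0)
  expect_true(median(offsets(rs$result)) <= 20)

  # predictive, steep trace (decay < lag / ln 2): offsets reach ~zero.
  # A longer chain (6 neurons), so that neurons with a full complement of
  # sequence predecessors dominate the median; the first neurons of the
  # chain have no predecessor to map onto and keep larger offsets.
  trSteep <- eligibilityTrace("exponential", decayTime = 15)
  map6 <- randomInvertibleMap(6, 6, tauM = 25, tauA = 15, seed = 66)
  codeS2 <- generateStereotypedCode(6, 1, interBurstLag = 20,
                                    gap = trSteep@support + lp$tau)
  rs2 <- suppressWarnings(
    runMirroringExperiment(codeS2, map6, trSteep, nEpochs = 500,
                           convergenceTol = 1e-7, tailFrac = 0.05,
                           seed = 65))
  expect_true(abs(median(offsets(rs2$result))) <= 5)
})

test_that("peak ratios track the eligibility and reject mismatched runs", {
  # flat eligibility: variable and stereotyped mirroring gains coincide
  lp <- testLoop(seed = 71)
  flat <- eligibilityTrace("custom_table", table = rep(0.7, 201),
                           tableDt = 1)
  gap <- flat@support + lp$tau
  codeV <- generateVariableCode(4, 15, renditionLen = 8000, gap = gap,
                                seed = 72)
  rv <- suppressWarnings(
    runMirroringExperiment(codeV, lp$map, flat, nEpochs = 60,
                           rateScale = 1, seed = 73, maxLag = 50))
  codeS <- generateStereotypedCode(4, 1, interBurstLag = 20,
                                   renditionLen = 600, gap = gap)
  rs <- suppressWarnings(
    runMirroringExperiment(codeS, lp$map, flat, nEpochs = 500,
                           convergenceTol = 1e-7, tailFrac = 0.05,
                           seed = 74, maxLag = 50))
  expect_equal(peakRatio(rv$result, rs$result), 1, tolerance = 0.15)

  # runs under different traces cannot be compared
  other <- suppressWarnings(
    runMirroringExperiment(codeV, lp$map, lp$trace, nEpochs = 5,
                           seed = 75))
  expect_error(peakRatio(other$result, rs$result), "config mismatch")
})

test_that("the shuffle null flags flat correlograms only", {
  code <- generateVariableCode(2, 10, renditionLen = 500, seed = 81)
  m <- rates(code)
  pb <- cbind(matrix(0, 2, 40), m[, 1:(ncol(m) - 40)])
  res <- mirroringOffset(code, pb, maxLag = 80, nNull = 50, seed = 82)
  expect_false(any(res@flat))
  set.seed(83)
  noise <- matrix(runif(length(m)), nrow(m))
  expect_warning(resN <- mirroringOffset(code, noise, maxLag = 80,
                                         nNull = 50, seed = 84),
                 "flat correlogram")
  expect_true(any(resN@flat))
})
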