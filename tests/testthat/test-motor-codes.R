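test_that("variable codes are square unit bursts with valid renditions", {
  code <- generateVariableCode(3, 20, renditionLen = 500, t0 = 10, dt = 1,
                               seed = 7)
  r <- rates(code)
  expect_true(all(r %in% c(0, 1)))
  expect_identical(dim(r), c(3L, 20L * 500L))
  # each neuron has exactly one burst of t0/dt bins per rendition
  for (k in seq_along(renditions(code))) {
    idx <- IRanges::start(renditions(code))[k]:IRanges::end(renditions(code))[k]
    expect_equal(rowSums(r[, idx]), rep(10, 3))
    for (i in 1:3) {
      on <- which(r[i, idx] == 1)
      expect_equal(on, on[1]:(on[1] + 9))  # contiguous square pulse
    }
  }
  expect_error(generateVariableCode(2, 5, t0 = 0.5, dt = 1),
               "t0 < dt")
  expect_error(generateVariableCode(2, 5, renditionLen = 15, t0 = 10),
               "renditionLen")
})

test_that("single-pulse auto-correlation peaks at zero with width t0", {
  code <- generateVariableCode(1, 1, renditionLen = 200, t0 = 10, seed = 1)
  cc <- crossCorrelation(code, code, maxLag = 50)
  v <- corValues(cc)[1, 1, ]
  l <- lags(cc)
  expect_equal(l[which.max(v)], 0)
  # full width at half maximum = t0, up to bin resolution and the small
  # baseline shift from full-window mean subtraction
  half <- which(v >= max(v) / 2)
  expect_lte(abs(diff(range(l[half])) - 10), 2 + 1e-9)
})

test_that("variable-code cross-correlograms are flat for distinct neurons", {
  code <- generateVariableCode(2, 200, renditionLen = 500, t0 = 10, dt = 1,
                               seed = 11)
  cc <- crossCorrelation(code, code, maxLag = 50)
  obs <- mean(corValues(cc)[1, 2, ])
  # shuffled-rendition null: permute neuron 2's renditions
  r <- rates(code)
  spans <- lapply(seq_along(renditions(code)), function(k)
    IRanges::start(renditions(code))[k]:IRanges::end(renditions(code))[k])
  set.seed(99)
  null <- replicate(20, {
    y <- r[2, , drop = FALSE]
    perm <- sample(length(spans))
    for (k in seq_along(spans)) y[1, spans[[k]]] <- r[2, spans[[perm[k]]]]
    ccn <- crossCorrelation(r[1, , drop = FALSE], y, maxLag = 50, dt = 1)
    mean(corValues(ccn)[1, 1, ])
  })
  expect_lte(abs(obs), 3 * sd(null) + 1e-12)
})

test_that("cross-correlation matches the nested-loop oracle exactly", {
  set.seed(5)
  x <- matrix(runif(200), 1)
  y <- matrix(runif(200), 1)
  cc <- crossCorrelation(x, y, maxLag = 50, dt = 1)
  expect_equal(corValues(cc)[1, 1, ], oracleXcov(x[1, ], y[1, ], 50),
               tolerance = 1e-12)
  # symmetry C_ij(s) = C_ji(-s)
  m <- rbind(x, y)
  ccm <- crossCorrelation(m, m, maxLag = 30, dt = 1)
  expect_equal(corValues(ccm)[1, 2, ], rev(corValues(ccm)[2, 1, ]),
               tolerance = 1e-12)
})

test_that("pure shifts and identity behave as expected under pearson", {
  set.seed(6)
  x <- runif(300)
  xs <- c(rep(0, 7), x[1:293])
  cc <- crossCorrelation(matrix(x, 1), matrix(xs, 1), maxLag = 20,
                         normalization = "pearson", dt = 1)
  expect_equal(lags(cc)[which.max(corValues(cc)[1, 1, ])], 7)
  cid <- crossCorrelation(matrix(x, 1), matrix(x, 1), maxLag = 20,
                          normalization = "pearson", dt = 1)
  k0 <- which(lags(cid) == 0)
  expect_equal(corValues(cid)[1, 1, k0], 1, tolerance = 1e-12)
  # constant signal: undefined correlation, not a division by zero
  expect_warning(
    ccc <- crossCorrelation(matrix(1, 1, 300), matrix(x, 1), maxLag = 5,
                            normalization = "pearson", dt = 1),
    "constant")
  expect_true(all(is.na(corValues(ccc))))
})

test_that("stereotyped codes put correlogram peaks at inter-burst lags", {
  code <- generateStereotypedCode(3, 5, interBurstLag = 20, t0 = 10,
                                  renditionLen = 200, gap = 100)
  cc <- crossCorrelation(code, code, maxLag = 60)
  l <- lags(cc)
  for (i in 1:3) for (j in 1:3) {
    v <- cc@values[i, j, ]
    expect_equal(l[which.max(v)], (j - i) * 20)  # b-lags-a convention
  }
  expect_equal(abs(l[which.max(cc@values[1, 3, ])]), 40)
  # degenerate lag: all neurons coactive, all peaks at 0
  c0 <- generateStereotypedCode(3, 3, interBurstLag = 0, t0 = 10,
                                renditionLen = 50, gap = 50)
  cc0 <- crossCorrelation(c0, c0, maxLag = 20)
  for (i in 1:3) for (j in 1:3)
    expect_equal(lags(cc0)[which.max(cc0@values[i, j, ])], 0)
  expect_error(generateStereotypedCode(4, 1, interBurstLag = 20,
                                       renditionLen = 50),
               "does not fit")
})

test_that("stereotyped auto-correlation width at half maximum is t0", {
  code <- generateStereotypedCode(4, 10, interBurstLag = 20, t0 = 10,
                                  renditionLen = 150, gap = 100)
  cc <- crossCorrelation(code, code, maxLag = 30)
  v <- corValues(cc)[2, 2, ]
  l <- lags(cc)
  half <- which(v >= max(v) / 2)
  expect_lte(abs(diff(range(l[half])) - 10), 2 + 1e-9)
})
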