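test_that("leadfield has unit-norm columns, full row rank and is reproducible", {
  lf <- makeLeadfield(4, 10, seed = 1)
  G <- gainMatrix(lf)
  expect_equal(dim(G), c(4L, 10L))
  expect_equal(qr(G)$rank, 4L)
  expect_equal(sqrt(colSums(G^2)), rep(1, 10), tolerance = 1e-12)

  # square case is invertible (full row rank on a square matrix)
  Gsq <- gainMatrix(makeLeadfield(6, 6, seed = 3))
  expect_gt(abs(det(Gsq)), 0)

  expect_identical(gainMatrix(makeLeadfield(8, 50, seed = 7)),
                   gainMatrix(makeLeadfield(8, 50, seed = 7)))
})

test_that("band sources realize the requested band-power proportions", {
  sf <- 250; n <- 500
  bands <- list(theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30))
  measure <- function(x) {
    pw <- vapply(bands, function(b)
      rhenet:::fftBandPower(x, sf, b[1], b[2]), numeric(1))
    pw / sum(pw)
  }
  # degenerate proportion: all power in theta
  x <- simulateBandSource(c(1, 0, 0), 100, n, sf, seed = 2)
  expect_gt(measure(x)["theta"], 0.95)
  expect_equal(sum(x^2), 100, tolerance = 1e-9)

  # generic mixture, proportions recovered within the 5% contract
  x <- simulateBandSource(c(0.5, 0.25, 0.25), 300, n, sf, seed = 3)
  expect_equal(unname(measure(x)), c(0.5, 0.25, 0.25), tolerance = 0.05)

  expect_error(simulateBandSource(c(-0.1, 0.6, 0.5), 1, n, sf), "nonnegative")
  expect_error(simulateBandSource(c(0.5, 0.4, 0.2), 1, n, sf), "sum to 1")
})

test_that("analytic entropy of configured proportions is recovered from the signal", {
  # realized 2 s signal, band powers measured on the waveform, entropy from
  # the entropy module
  x <- simulateBandSource(c(0.5, 0.25, 0.25), 500, 500, 250, seed = 11)
  pw <- vapply(list(c(4, 8), c(8, 13), c(13, 30)), function(b)
    rhenet:::fftBandPower(x, 250, b[1], b[2]), numeric(1))
  en <- rhythmEntropy(normalizePowers(pw[1], pw[2], pw[3]))
  expect_equal(en, 1.5, tolerance = 0.1)
  # uniform proportions maximize the entropy
  expect_equal(rhythmEntropy(c(1, 1, 1) / 3), log2(3), tolerance = 1e-12)
})

test_that("VAR node simulation enforces stability and reports true edges", {
  co <- array(0, c(2, 2, 1))
  co[1, 1, 1] <- 0.5; co[2, 2, 1] <- 0.2; co[2, 1, 1] <- 0.5
  sim <- simulateMvarNodes(co, 500, seed = 1)
  expect_equal(dim(sim$series), c(2L, 500L))
  expect_equal(sim$edges, matrix(c(0, 1, 0, 0), 2, 2))

  coZero <- array(0, c(3, 3, 1)); diag(coZero[, , 1]) <- 0.4
  expect_equal(sum(simulateMvarNodes(coZero, 100, seed = 2)$edges), 0)

  bad <- array(0, c(2, 2, 1)); diag(bad[, , 1]) <- 1.05
  expect_error(simulateMvarNodes(bad, 100), "spectral radius")

  expect_identical(simulateMvarNodes(co, 300, seed = 9)$series,
                   simulateMvarNodes(co, 300, seed = 9)$series)
})

test_that("simulated datasets keep their bookkeeping contracts", {
  cfg <- simConfig(nTrialsPerClass = 20, seed = 4)
  ds <- simulateDataset(cfg)
  expect_equal(nTrials(ds$epochs), 40L)
  expect_equal(as.vector(table(trialLabels(ds$epochs))), c(20L, 20L))

  # determinism: identical config implies bit-identical output
  ds2 <- simulateDataset(cfg)
  expect_identical(epochData(ds$epochs), epochData(ds2$epochs))
  expect_identical(reactionTimes(ds$truth), reactionTimes(ds2$truth))

  # ground-truth entropy is the analytic value of the configured proportions
  expect_identical(ds$truth@classEntropy[["error"]],
                   rhythmEntropy(cfg@bandPropsError))
  expect_identical(ds$truth@classEntropy[["correct"]], log2(3))

  # error reaction times exceed correct ones on average
  lab <- trialLabels(ds$epochs)
  expect_gt(mean(reactionTimes(ds$epochs)[lab == "error"]),
            mean(reactionTimes(ds$epochs)[lab == "correct"]))

  expect_error(simulateDataset(simConfig(epochLen = 0.3)), "too short")
})

test_that("scalp signal-to-noise power ratio honours the configured SNR", {
  # same seed with essentially no sensor noise isolates the signal component
  cfgClean <- simConfig(epochLen = 2, sensorSnr = 1e12, seed = 21)
  cfgNoisy <- simConfig(epochLen = 2, sensorSnr = 10, seed = 21)
  clean <- epochData(simulateDataset(cfgClean)$epochs)
  noisy <- epochData(simulateDataset(cfgNoisy)$epochs)
  sigP <- mean(clean^2)
  noiseP <- mean((noisy - clean)^2)
  expect_equal(sigP / noiseP, 10, tolerance = 0.1)
})
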